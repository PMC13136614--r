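#' Kinetic parameters of the biomass and FLEX metabolite models
#'
#' Constructor with defaults set to the parameter values identified for a
#' CHO fed-batch process (the reference parameter set used throughout the
#' package, including by the synthetic-data generator). Internal time unit is
#' days; concentrations g/l; cell densities 1e6 cells/ml; specific rates
#' g/1e9 cells/d.
#'
#' @param kd base death rate (1/d).
#' @param kTd death toxicity factor (per unit biomaterial, 1/d).
#' @param kl base lysis rate (1/d).
#' @param kTl lysis toxicity factor (per 1e6 lysed cells/ml, 1/d).
#' @param YG glucose yield on effective growth (dimensionless).
#' @param KG glucose half-saturation (g/l).
#' @param KI lactate inhibition constant (g/l).
#' @param mGlc glucose maintenance coefficient (g/1e9 cells/d).
#' @param vOx_max maximum oxidative capacity (g/1e9 cells/d).
#' @param KLac lactate reuptake half-saturation (g/l).
#' @param YLac_Prod,YLac_Cons lactate production/consumption yields.
#' @param YGlu glutamate yield on growth.
#' @param KGlu glutamate half-saturation (g/l).
#' @param mGlu glutamate maintenance coefficient (g/1e9 cells/d).
#' @param vGln_max maximum glutamine uptake (g/1e9 cells/d).
#' @param KGln glutamine half-saturation (g/l).
#' @param YN_Glu,YN_Gln ammonium yields from glutamate/glutamine catabolism.
#' @return a named list of class `kinetic_parameters`.
#' @export
kinetic_parameters <- function(kd = 0.01794129, kTd = 0.00033013,
                               kl = 0.02962941, kTl = 0.01359236,
                               YG = 13.2705431, KG = 25.4521167,
                               KI = 8.18034685, mGlc = 0.882132146,
                               vOx_max = 1.64619067, KLac = 53.1522878,
                               YLac_Prod = 2.56537542, YLac_Cons = 1.17984249,
                               YGlu = 2.99191279e-07, KGlu = 0.00151171924,
                               mGlu = 0.00926153436, vGln_max = 2.68030547,
                               KGln = 2.69282272, YN_Glu = 20.8763687,
                               YN_Gln = 0.722160623) {
  p <- as.list(environment())
  stopifnot(all(unlist(p) >= 0), KG > 0, KI > 0, KLac > 0, KGlu > 0, KGln > 0)
  structure(p, class = c("kinetic_parameters", "list"))
}

#' Death and lysis rates
#'
#' Base rates modulated by toxicity terms: death accelerates with accumulated
#' biomaterial, lysis with the lysed-cell pool.
#'
#' @param state list/vector with `gammaX` (1e6 cells.d/ml) and `Xl`
#'   (1e6 cells/ml).
#' @param params a [kinetic_parameters()].
#' @return c(mu_d, mu_l) in 1/d.
#' @export
death_lysis_rates <- function(state, params) {
  mu_d <- params$kd + params$kTd * state[["gammaX"]]
  mu_l <- params$kl + params$kTl * state[["Xl"]]
  c(mu_d = mu_d, mu_l = mu_l)
}

#' Effective growth rate
#'
#' The effective biomass-synthesis rate is the net observed growth rate plus
#' death and lysis losses. Values below zero are truncated at 1e-6 per day
#' (all rates here are per day).
#'
#' @param mu_net net growth rate (1/d).
#' @param mu_d,mu_l death and lysis rates (1/d).
#' @return mu_eff (1/d).
#' @export
effective_growth <- function(mu_net, mu_d, mu_l) {
  pmax(mu_net + mu_d + mu_l, 1e-6)
}

#' Specific glucose consumption rate
#'
#' Growth-linked uptake with substrate saturation (squared tanh saturation),
#' cubic lactate inhibition, and a maintenance term. Returned as a positive
#' consumption magnitude.
#'
#' @param Glc,Lac concentrations (g/l).
#' @param mu_eff effective growth rate (1/d).
#' @param params a [kinetic_parameters()].
#' @return vGlc (g/1e9 cells/d), positive = consumed.
#' @export
rate_glc <- function(Glc, Lac, mu_eff, params) {
  params$YG * mu_eff * tanh((Glc / params$KG)^2) /
    ((Lac / params$KI)^3 + 1) + params$mGlc
}

#' Net specific lactate rate (overflow metabolism)
#'
#' Lactate is produced when glucose uptake exceeds the oxidative capacity and
#' consumed (with saturable reuptake) when capacity exceeds uptake; the two
#' branches are mutually exclusive.
#'
#' @param vGlc glucose consumption magnitude (g/1e9 cells/d).
#' @param Lac lactate concentration (g/l).
#' @param params a [kinetic_parameters()].
#' @return net vLac (g/1e9 cells/d), positive = produced.
#' @export
rate_lac <- function(vGlc, Lac, params) {
  prod <- pmax(0, vGlc - params$vOx_max)
  cons <- pmax(0, params$vOx_max - vGlc) * tanh((Lac / params$KLac)^2)
  params$YLac_Prod * prod - params$YLac_Cons * cons
}

#' Specific glutamate consumption rate
#' @param Glu glutamate (g/l); @param mu_eff 1/d; @param params parameters.
#' @return vGlu (g/1e9 cells/d), positive = consumed.
#' @export
rate_glu <- function(Glu, mu_eff, params) {
  params$YGlu * mu_eff * tanh((Glu / params$KGlu)^2) + params$mGlu
}

#' Specific glutamine consumption rate
#' @param Gln glutamine (g/l); @param params parameters.
#' @return vGln (g/1e9 cells/d), positive = consumed.
#' @export
rate_gln <- function(Gln, params) {
  params$vGln_max * tanh((Gln / params$KGln)^2)
}

#' Specific ammonium production rate
#'
#' By-product of glutamate and glutamine catabolism.
#' @param vGlu,vGln consumption magnitudes (g/1e9 cells/d).
#' @param params parameters.
#' @return vNH4 (g/1e9 cells/d), positive = produced.
#' @export
rate_nh4 <- function(vGlu, vGln, params) {
  params$YN_Glu * vGlu + params$YN_Gln * vGln
}

#' Population balance right-hand side
#'
#' Viable, dead and lysed cell pools plus the cumulative biomaterial. Feeding
#' dilutes all cell pools and the biomaterial (density decreases when volume
#' is added).
#'
#' @param state named vector Xv, Xd, Xl, gammaX.
#' @param params a [kinetic_parameters()].
#' @param mu_eff effective growth rate (1/d).
#' @param F_over_V dilution rate (1/d).
#' @return named derivative vector (per day).
#' @export
population_rhs <- function(state, params, mu_eff, F_over_V = 0) {
  r <- death_lysis_rates(state, params)
  Xv <- state[["Xv"]]
  c(Xv = (mu_eff - r[["mu_d"]] - r[["mu_l"]]) * Xv - F_over_V * Xv,
    Xd = r[["mu_d"]] * Xv - F_over_V * state[["Xd"]],
    Xl = r[["mu_l"]] * Xv - F_over_V * state[["Xl"]],
    gammaX = Xv - F_over_V * state[["gammaX"]])
}

#' FLEX metabolite right-hand side
#'
#' Five extracellular metabolites driven by signed specific rates times the
#' viable cell density, plus feed/washout dilution. Glucose, glutamine and
#' glutamate carry feed source terms; lactate and ammonium are washout-only.
#'
#' @param state named vector Glc, Lac, Gln, Glu, NH4 (g/l).
#' @param params a [kinetic_parameters()].
#' @param mu_eff effective growth rate (1/d).
#' @param Xv viable cell density (1e6 cells/ml).
#' @param feed list with `F` (ml/d), `V` (ml), `Glc_in`, `Gln_in`, `Glu_in`
#'   (g/l); all zero for an unfed interval.
#' @return named derivative vector (g/l/d).
#' @export
flex_rhs <- function(state, params, mu_eff, Xv,
                     feed = list(F = 0, V = 1, Glc_in = 0, Gln_in = 0,
                                 Glu_in = 0)) {
  vGlc <- rate_glc(state[["Glc"]], state[["Lac"]], mu_eff, params)
  vLac <- rate_lac(vGlc, state[["Lac"]], params)
  vGlu <- rate_glu(state[["Glu"]], mu_eff, params)
  vGln <- rate_gln(state[["Gln"]], params)
  vNH4 <- rate_nh4(vGlu, vGln, params)
  FV <- feed$F / feed$V
  cell <- c(Glc = -vGlc, Lac = vLac, Gln = -vGln, Glu = -vGlu,
            NH4 = vNH4) * Xv
  # smooth depletion cut-off: cellular consumption fades out as a pool
  # approaches zero (scale 1e-3 g/l), keeping states non-negative and the
  # system non-stiff at depletion; dilution terms vanish with C naturally
  s <- unlist(state[names(cell)])
  dep <- s / (s + 1e-3)
  cell <- ifelse(cell < 0, cell * dep, cell)
  cell + c(Glc = FV * (feed$Glc_in - s[["Glc"]]),
           Lac = -FV * s[["Lac"]],
           Gln = FV * (feed$Gln_in - s[["Gln"]]),
           Glu = FV * (feed$Glu_in - s[["Glu"]]),
           NH4 = -FV * s[["NH4"]])
}

#' Integrate an ODE system with bolus feed events
#'
#' Integrates `rhs(t, y)` segment-by-segment between bolus events with an
#' adaptive stiff-capable method, applying instantaneous state jumps at event
#' times. Time unit: days.
#'
#' @param rhs function(t, y) returning dy/dt (named vector).
#' @param y0 named initial state.
#' @param times output time grid (d), strictly increasing.
#' @param events data.frame with columns `time` (d) and a `jump` function
#'   stored in the list-column `fun`: each `fun(y)` returns the post-event
#'   state. NULL for none.
#' @param rtol,atol integrator tolerances.
#' @return matrix of states at `times` (rows), column `time` first.
#' @export
integrate_events <- function(rhs, y0, times, events = NULL,
                             rtol = 1e-8, atol = 1e-10) {
  deriv <- function(t, y, parms) list(rhs(t, y))
  ev_times <- if (is.null(events)) numeric() else sort(events$time)
  ev_times <- ev_times[ev_times > times[1] & ev_times <= times[length(times)]]
  breaks <- sort(unique(c(times, ev_times)))
  out <- matrix(NA_real_, length(times), length(y0) + 1,
                dimnames = list(NULL, c("time", names(y0))))
  y <- y0
  seg_start <- breaks[1]
  if (seg_start %in% times) out[match(seg_start, times), ] <- c(seg_start, y)
  for (i in seq_along(breaks)[-1]) {
    seg <- c(seg_start, breaks[i])
    if (diff(seg) > 1e-12) {
      sol <- deSolve::ode(y, seg, deriv, NULL, method = "lsoda",
                          rtol = rtol, atol = atol, maxsteps = 50000)
      y <- sol[nrow(sol), -1]
      if (any(!is.finite(y))) {
        bad <- names(y)[!is.finite(y)][1]
        stop(sprintf("non-finite ODE state '%s' at t = %.3f d", bad, seg[2]))
      }
      y <- pmax(y, 0)
    }
    if (!is.null(events)) {
      hit <- which(abs(events$time - breaks[i]) < 1e-9)
      for (h in hit) y <- events$fun[[h]](y)
    }
    if (breaks[i] %in% times) out[match(breaks[i], times), ] <- c(breaks[i], y)
    seg_start <- breaks[i]
  }
  out
}

#' Simulate the population balance model
#'
#' @param y0 named initial state (Xv, Xd, Xl, gammaX).
#' @param times_d output grid in days.
#' @param params a [kinetic_parameters()].
#' @param mu_eff_fun function(t_d) -> effective growth rate (1/d).
#' @param FV_fun function(t_d) -> dilution rate (1/d), default 0.
#' @return state matrix as from [integrate_events()].
#' @export
simulate_population <- function(y0, times_d, params, mu_eff_fun,
                                FV_fun = function(t) 0) {
  integrate_events(function(t, y) {
    population_rhs(y, params, mu_eff_fun(t), FV_fun(t))
  }, y0, times_d)
}

#' Simulate the FLEX metabolite model with imposed cell dynamics
#'
#' @param y0 named initial concentrations (Glc, Lac, Gln, Glu, NH4).
#' @param times_d output grid (days).
#' @param params a [kinetic_parameters()].
#' @param mu_eff_fun,Xv_fun functions of time (d) giving mu_eff (1/d) and
#'   viable cell density (1e6 cells/ml).
#' @param feed_events optional data.frame(time, fun) of bolus jumps, as in
#'   [integrate_events()].
#' @return state matrix at `times_d`.
#' @export
simulate_flex <- function(y0, times_d, params, mu_eff_fun, Xv_fun,
                          feed_events = NULL) {
  integrate_events(function(t, y) {
    flex_rhs(y, params, mu_eff_fun(t), Xv_fun(t))
  }, y0, times_d, events = feed_events)
}

#' Precompute a fixed-step integration plan for the FLEX model
#'
#' Parameter identification needs thousands of FLEX simulations; everything
#' that does not depend on the kinetic parameters (effective growth and
#' viable-cell values at the Runge-Kutta stage times, and the affine
#' concentration maps of the bolus feed events) is precomputed once here.
#'
#' @param times_d sampling times (d).
#' @param mu_eff_fun,Xv_fun functions of time (d).
#' @param feed_events data.frame(time, fun) of FLEX jumps (may be NULL);
#'   each jump must be affine and diagonal in the concentration vector.
#' @param h target step (d).
#' @return opaque plan list consumed by [flex_simulate_plan()].
#' @export
flex_plan <- function(times_d, mu_eff_fun, Xv_fun, feed_events = NULL,
                      h = 0.05) {
  mets <- c("Glc", "Lac", "Gln", "Glu", "NH4")
  segs <- list()
  for (k in seq_along(times_d)[-1]) {
    t0 <- times_d[k - 1]; t1 <- times_d[k]
    ev <- NULL
    if (!is.null(feed_events)) {
      i <- which(feed_events$time > t0 & feed_events$time <= t0 + 1e-5)
      if (length(i)) {
        f <- feed_events$fun[[i[1]]]
        bvec <- f(stats::setNames(rep(0, 5), mets))
        avec <- vapply(seq_len(5), function(j) {
          e <- stats::setNames(rep(0, 5), mets); e[j] <- 1
          (f(e) - bvec)[j]
        }, numeric(1))
        ev <- list(a = avec, b = unname(bvec))
      }
    }
    n_sub <- max(1L, ceiling((t1 - t0) / h))
    hh <- (t1 - t0) / n_sub
    tg <- t0 + hh * (seq_len(n_sub) - 1)
    segs[[k - 1]] <- list(
      event = ev, h = hh, n = n_sub,
      mu0 = mu_eff_fun(tg), mu_half = mu_eff_fun(tg + hh / 2),
      mu1 = mu_eff_fun(tg + hh),
      xv0 = Xv_fun(tg), xv_half = Xv_fun(tg + hh / 2),
      xv1 = Xv_fun(tg + hh))
  }
  list(times_d = times_d, segments = segs, mets = mets)
}

flex_rates_vec <- function(C, params, mu_eff, Xv) {
  vGlc <- rate_glc(C[1], C[2], mu_eff, params)
  vLac <- rate_lac(vGlc, C[2], params)
  vGlu <- rate_glu(C[4], mu_eff, params)
  vGln <- rate_gln(C[3], params)
  vNH4 <- rate_nh4(vGlu, vGln, params)
  d <- c(-vGlc, vLac, -vGln, -vGlu, vNH4) * Xv
  # smooth depletion cut-off, as in flex_rhs
  dep <- C / (C + 1e-3)
  ifelse(d < 0, d * dep, d)
}

#' Simulate the FLEX model on a precomputed plan (fixed-step RK4)
#'
#' @param C0 named initial concentrations (Glc, Lac, Gln, Glu, NH4).
#' @param plan from [flex_plan()].
#' @param params a [kinetic_parameters()].
#' @return matrix of pre-feed concentrations at `plan$times_d`.
#' @export
flex_simulate_plan <- function(C0, plan, params) {
  mets <- plan$mets
  # unpack once; the stage function works on plain doubles for speed
  YG <- params$YG; KG <- params$KG; KI <- params$KI; mGlc <- params$mGlc
  vOx <- params$vOx_max; KLac <- params$KLac
  YLp <- params$YLac_Prod; YLc <- params$YLac_Cons
  YGlu <- params$YGlu; KGlu <- params$KGlu; mGlu <- params$mGlu
  vGmax <- params$vGln_max; KGln <- params$KGln
  YNu <- params$YN_Glu; YNn <- params$YN_Gln
  f <- function(C, mu, xv) {
    vGlc <- YG * mu * tanh((C[1] / KG)^2) / ((C[2] / KI)^3 + 1) + mGlc
    ex <- vGlc - vOx
    vLac <- if (ex > 0) YLp * ex else YLc * ex * tanh((C[2] / KLac)^2)
    vGlu <- YGlu * mu * tanh((C[4] / KGlu)^2) + mGlu
    vGln <- vGmax * tanh((C[3] / KGln)^2)
    d <- c(-vGlc, vLac, -vGln, -vGlu, YNu * vGlu + YNn * vGln) * xv
    dep <- C / (C + 1e-3)
    ifelse(d < 0, d * dep, d)
  }
  out <- matrix(NA_real_, length(plan$times_d), 5,
                dimnames = list(NULL, mets))
  C <- unname(C0[mets])
  out[1, ] <- C
  for (k in seq_along(plan$segments)) {
    sg <- plan$segments[[k]]
    if (!is.null(sg$event)) C <- sg$event$a * C + sg$event$b
    h <- sg$h; h2 <- h / 2; h6 <- h / 6
    mu0 <- sg$mu0; muh <- sg$mu_half; mu1 <- sg$mu1
    x0 <- sg$xv0; xh <- sg$xv_half; x1 <- sg$xv1
    for (i in seq_len(sg$n)) {
      k1 <- f(C, mu0[i], x0[i])
      k2 <- f(C + h2 * k1, muh[i], xh[i])
      k3 <- f(C + h2 * k2, muh[i], xh[i])
      k4 <- f(C + h * k3, mu1[i], x1[i])
      C <- C + h6 * (k1 + 2 * k2 + 2 * k3 + k4)
      C[C < 0] <- 0
    }
    out[k + 1, ] <- C
  }
  out
}

log_pack <- function(params, names) log(unlist(params[names]))
log_unpack <- function(theta, params, names) {
  params[names] <- as.list(exp(theta))
  params
}

#' Identify population-model parameters by Nelder-Mead
#'
#' Fits (kd, kTd, kl, kTl) to viable and dead cell trajectories. The viable
#' pool is simulated with the measured net growth rate, so the free
#' parameters are informed by the dead-cell trajectory plus a soft penalty
#' keeping dead and lysed pools within a factor of ~3 of each other
#' (lysed cells are unobservable with a trypan-blue assay).
#'
#' @param batches list of lists, each with `times_d`, `Xv`, `Xd` (vectors),
#'   `mu_net_fun` (function of t_d, 1/d), and optionally `events`
#'   (feed-dilution jumps as from [dilution_events()]).
#' @param params_init starting [kinetic_parameters()].
#' @param lambda weight of the dead/lysed comparability penalty.
#' @param maxit Nelder-Mead iteration budget (0 returns the initial guess).
#' @param n_starts random multi-starts around the initial guess.
#' @param seed seed for the multi-start jitter.
#' @return list with `params` (full set, 4 population entries updated),
#'   `sse`, `convergence`.
#' @export
identify_population <- function(batches, params_init = kinetic_parameters(),
                                lambda = 1, maxit = 500, n_starts = 3,
                                seed = 1) {
  nm <- c("kd", "kTd", "kl", "kTl")
  objective <- function(theta) {
    p <- log_unpack(theta, params_init, nm)
    tot <- 0
    for (b in batches) {
      mu_eff_fun <- NULL
      sim <- try(integrate_events(function(t, y) {
        r <- death_lysis_rates(y, p)
        mu_eff <- effective_growth(b$mu_net_fun(t), r[["mu_d"]], r[["mu_l"]])
        population_rhs(y, p, mu_eff, 0)
      }, c(Xv = b$Xv[1], Xd = b$Xd[1], Xl = b$Xd[1] * 0.5,
           gammaX = 0), b$times_d, events = b$events,
      rtol = 1e-6, atol = 1e-8),
      silent = TRUE)
      if (inherits(sim, "try-error")) return(1e10)
      tot <- tot + sum((sim[, "Xv"] - b$Xv)^2) + sum((sim[, "Xd"] - b$Xd)^2)
      ratio <- log(pmax(sim[, "Xl"], 1e-12) / pmax(sim[, "Xd"], 1e-12))
      tot <- tot + lambda * sum(pmax(0, abs(ratio) - log(3))^2)
    }
    tot
  }
  fit_from <- function(theta0) {
    if (maxit == 0) {
      return(list(par = theta0, value = objective(theta0), convergence = 0))
    }
    stats::optim(theta0, objective, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-10))
  }
  theta0 <- log_pack(params_init, nm)
  set.seed(seed)
  starts <- c(list(theta0),
              replicate(max(0, n_starts - 1),
                        theta0 + stats::rnorm(length(theta0), 0, 0.1),
                        simplify = FALSE))
  fits <- lapply(starts, fit_from)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  list(params = log_unpack(best$par, params_init, nm),
       sse = best$value, convergence = best$convergence)
}

#' Identify FLEX metabolite parameters by Nelder-Mead
#'
#' Joint least-squares fit of the 15 FLEX parameters across batches, with
#' viable-cell dynamics and effective growth imposed. Strictly positive
#' parameters are optimised on the log scale; multi-start with the best-SSE
#' winner.
#'
#' @param batches list of lists with `times_d`, concentration matrix `conc`
#'   (columns Glc, Lac, Gln, Glu, NH4 observed at `times_d`), `mu_eff_fun`,
#'   `Xv_fun`, optional `feed_events`.
#' @param params_init starting [kinetic_parameters()].
#' @param maxit iteration budget per start.
#' @param n_starts number of seeded multi-starts.
#' @param seed jitter seed.
#' @param exclude optional metabolite names dropped from the objective.
#' @return list with `params`, `sse`, `per_metabolite` (SSE and R2),
#'   `convergence`.
#' @export
identify_flex <- function(batches, params_init = kinetic_parameters(),
                          maxit = 2000, n_starts = 3, seed = 1,
                          exclude = character(), h = 0.05) {
  nm <- c("YG", "KG", "KI", "mGlc", "vOx_max", "KLac", "YLac_Prod",
          "YLac_Cons", "YGlu", "KGlu", "mGlu", "vGln_max", "KGln",
          "YN_Glu", "YN_Gln")
  mets <- setdiff(c("Glc", "Lac", "Gln", "Glu", "NH4"), exclude)
  plans <- lapply(batches, function(b) {
    flex_plan(b$times_d, b$mu_eff_fun, b$Xv_fun, b$feed_events, h = h)
  })
  simulate_all <- function(p) {
    lapply(seq_along(batches), function(i) {
      flex_simulate_plan(batches[[i]]$conc[1, ], plans[[i]], p)
    })
  }
  objective <- function(theta) {
    p <- log_unpack(theta, params_init, nm)
    sims <- simulate_all(p)
    tot <- 0
    for (i in seq_along(batches)) {
      if (any(!is.finite(sims[[i]]))) return(1e10)
      tot <- tot + sum((sims[[i]][, mets] - batches[[i]]$conc[, mets])^2)
    }
    tot
  }
  theta0 <- log_pack(params_init, nm)
  set.seed(seed)
  starts <- c(list(theta0),
              replicate(max(0, n_starts - 1),
                        theta0 + stats::rnorm(length(theta0), 0, 0.2),
                        simplify = FALSE))
  fits <- lapply(starts, function(t0) {
    if (maxit == 0) {
      return(list(par = t0, value = objective(t0), convergence = 0))
    }
    f <- stats::optim(t0, objective, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-10))
    # one polishing restart from the incumbent simplex collapse
    stats::optim(f$par, objective, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-10))
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  p_hat <- log_unpack(best$par, params_init, nm)
  sims <- simulate_all(p_hat)
  per_met <- do.call(rbind, lapply(c("Glc", "Lac", "Gln", "Glu", "NH4"),
    function(m) {
      obs <- unlist(lapply(batches, function(b) b$conc[, m]))
      pred <- unlist(lapply(sims, function(s) s[, m]))
      sse <- sum((pred - obs)^2)
      sstot <- sum((obs - mean(obs))^2)
      data.frame(metabolite = m, sse = sse,
                 r2 = if (sstot > 0) 1 - sse / sstot else NA_real_)
    }))
  list(params = p_hat, sse = best$value, per_metabolite = per_met,
       convergence = best$convergence)
}
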