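#' One explicit-Euler bioreactor mass-balance step
#'
#' `dE/dt = rE Xv - F E / V + F Ein / V`: cellular exchange plus feed
#' washout and feed supply, advanced one step.
#'
#' @param E extracellular concentration (g/l).
#' @param rE signed specific rate (g/1e9 cells/d; production positive).
#' @param Xv viable cell density (1e6 cells/ml).
#' @param F feed rate (ml/d).
#' @param V reactor volume (ml).
#' @param E_in feed concentration (g/l).
#' @param dt step (d).
#' @return updated concentration.
#' @export
mass_balance_step <- function(E, rE, Xv, F, V, E_in, dt) {
  stopifnot(V > 0, dt > 0)
  E + dt * (rE * Xv - F * E / V + F * E_in / V)
}

#' Run the integrated digital twin
#'
#' Fully predictive simulation from initial concentrations and a feed
#' schedule alone: per 0.1-d step the growth network predicts the net
#' growth rate (biomaterial recurrence self-fed), the kinetic layer
#' supplies death/lysis rates, the effective growth rate and the five FLEX
#' metabolite rates, and PC-dFBA - hard-bounded by those predictions -
#' predicts the remaining exchange fluxes and the product titer. All
#' concentrations advance through the bioreactor mass balance; bolus feeds
#' dilute cells and add mass at their scheduled times. No measured data
#' after time zero is consulted.
#'
#' @param init named list/vector: concentrations for the analyte panel
#'   (including `VCD`), and optionally `Xd`, `Xl`, `gammaX`, `V` (ml).
#' @param feeds data.frame(time_d, stream, volume_ml).
#' @param compositions data.frame(stream, analyte, conc_g_per_l).
#' @param artifacts list with `growth_model`, `params`
#'   (a [kinetic_parameters()]), `loading_model`, `net` (reduced
#'   [metabolic_network()]), `band_fun` (from [band_statistics()]).
#' @param horizon end time (d).
#' @param dt coupling step (d).
#' @param conversion network-flux to specific-rate factor.
#' @param RF band relaxation factor.
#' @param score_bounds PCA score box.
#' @param hard_relax_frac relative widening of predicted hard bounds when
#'   the step LP is infeasible.
#' @return object of class `twin_result`: `states` (data.frame, one row per
#'   step), `diagnostics` (per-step LP status/relaxation), `floored`
#'   (concentration flooring events).
#' @export
run_twin <- function(init, feeds, compositions, artifacts, horizon,
                     dt = 0.1, conversion = 1, RF = 1.5,
                     score_bounds = c(-100, 100), hard_relax_frac = 0.5) {
  an <- chotwin_analytes()
  net <- artifacts$net
  params <- artifacts$params
  gm <- artifacts$growth_model
  lm <- artifacts$loading_model
  band_fun <- artifacts$band_fun
  amap <- net$analyte_map
  flex_rxn <- names(amap)[amap %in% an$flex]
  free_rxn <- setdiff(names(amap), flex_rxn)
  gmet <- an$growth_nn
  times <- seq(0, horizon, by = dt)
  conc <- stats::setNames(rep(0, length(an$all)), an$all)
  conc[names(init)[names(init) %in% an$all]] <-
    unlist(init[names(init) %in% an$all])
  Xd <- init$Xd %||% 0
  Xl <- init$Xl %||% 0
  gamma <- init$gammaX %||% 0
  V <- init$V %||% 10
  prev_flux <- NULL
  prev_rates <- stats::setNames(rep(0, length(an$all)), an$all)
  states <- vector("list", length(times))
  diags <- vector("list", length(times) - 1)
  floored <- list()
  for (i in seq_along(times)) {
    t <- times[i]
    states[[i]] <- c(time_d = t, conc, Xd = Xd, Xl = Xl, gammaX = gamma,
                     V = V)
    if (i == length(times)) break
    # (1) growth-rate prediction (self-fed biomaterial recurrence)
    x <- c(prev_rates[gmet], conc[gmet], gamma, t, dt)
    xs <- scale_apply(gm$scaler, matrix(x, 1))
    mu <- gm$baseline$fun(t) + mlp_forward(gm$net, xs)$y
    # (2) kinetic layer: death/lysis, effective growth, FLEX rates
    r <- death_lysis_rates(list(gammaX = gamma, Xl = Xl), params)
    mu_eff <- effective_growth(mu, r[["mu_d"]], r[["mu_l"]])
    vGlc <- rate_glc(conc[["Glc"]], conc[["Lac"]], mu_eff, params)
    vLac <- rate_lac(vGlc, conc[["Lac"]], params)
    vGlu <- rate_glu(conc[["Glu"]], mu_eff, params)
    vGln <- rate_gln(conc[["Gln"]], params)
    vNH4 <- rate_nh4(vGlu, vGln, params)
    flex_rates <- c(Glc = -vGlc, Lac = vLac, Gln = -vGln, Glu = -vGlu,
                    NH4 = vNH4)
    # (3) PC-dFBA with predicted hard bounds
    hb <- list()
    hb[[net$objective]] <- rep(mu_eff / conversion, 2)
    for (rx in flex_rxn) {
      hb[[rx]] <- rep(flex_rates[[amap[[rx]]]] / conversion, 2)
    }
    feat <- prev_rates
    feat[an$flex] <- flex_rates
    feat["VCD"] <- mu_eff
    L <- predict_loadings(lm, feat)
    # empirical band constrains only the dynamically predicted exchanges;
    # the FLEX + growth subset is governed by its (relaxable) hard bounds
    bstats <- lapply(stats::setNames(nm = unname(amap[free_rxn])),
                     band_fun, t = t)
    prob <- build_step_problem(net, L, hard_bounds = hb,
                               band_stats = bstats, RF = RF,
                               score_bounds = score_bounds)
    sol <- solve_step(prob, prev_flux = prev_flux)
    relaxed <- FALSE
    frac <- hard_relax_frac
    for (round in 1:6) {
      if (sol$status == "optimal") break
      wid <- lapply(hb, function(b) {
        c(b[1] - frac * (abs(b[1]) + 0.01),
          b[2] + frac * (abs(b[2]) + 0.01))
      })
      prob <- relax_hard_bounds(prob, wid)
      sol <- solve_step(prob, prev_flux = prev_flux)
      relaxed <- TRUE
      frac <- frac * 2
    }
    if (sol$status != "optimal") {
      stop(sprintf("twin: PC-dFBA layer infeasible at t = %.2f d", t))
    }
    diags[[i]] <- list(time_d = t, relaxed = relaxed,
                       objective = sol$objective,
                       penalty = sol$continuity_penalty, mu = mu,
                       mu_eff = mu_eff)
    # (4) mass-balance advance (Eq.-of-motion per analyte), cells, volume
    Xv <- conc[["VCD"]]
    rates_now <- stats::setNames(rep(0, length(an$all)), an$all)
    rates_now[an$flex] <- flex_rates
    for (rx in free_rxn) {
      rates_now[amap[[rx]]] <- sol$fluxes[[rx]] * conversion
    }
    for (a in setdiff(an$all, "VCD")) {
      newv <- mass_balance_step(conc[[a]], rates_now[[a]], Xv, 0, V, 0, dt)
      if (newv < 0) {
        floored[[length(floored) + 1L]] <- c(t = t, analyte = a)
        newv <- 0
      }
      conc[[a]] <- newv
    }
    conc[["VCD"]] <- Xv * (1 + mu * dt)
    Xd <- Xd + r[["mu_d"]] * Xv * dt
    Xl <- Xl + r[["mu_l"]] * Xv * dt
    gamma <- gamma + Xv * dt
    prev_rates <- rates_now
    prev_rates["VCD"] <- mu_eff
    prev_flux <- sol$fluxes
    # bolus feeds scheduled within (t, t+dt]
    evs <- feeds[feeds$time_d > t & feeds$time_d <= t + dt + 1e-12, ,
                 drop = FALSE]
    if (nrow(evs)) {
      evs <- evs[order(evs$time_d, evs$stream), ]
      for (j in seq_len(nrow(evs))) {
        vol <- evs$volume_ml[j]
        cin <- stats::setNames(rep(0, length(an$all)), an$all)
        rows <- compositions[compositions$stream == evs$stream[j], ]
        cin[rows$analyte[rows$analyte %in% an$all]] <-
          rows$conc_g_per_l[rows$analyte %in% an$all]
        mets <- setdiff(an$all, "VCD")
        conc[mets] <- (conc[mets] * V + cin[mets] * vol) / (V + vol)
        dil <- V / (V + vol)
        conc[["VCD"]] <- conc[["VCD"]] * dil
        Xd <- Xd * dil; Xl <- Xl * dil; gamma <- gamma * dil
        V <- V + vol
      }
    }
  }
  structure(list(states = as.data.frame(do.call(rbind, states)),
                 diagnostics = diags, floored = floored),
            class = "twin_result")
}

#' Score a simulation against observed data
#'
#' Interpolates simulated trajectories to the observation times and reports
#' per-analyte R2 (`1 - SSE/SStot`), SSE and natural-log SSE. Zero-variance
#' observation series yield `NA` R2.
#'
#' @param result a `twin_result` (or any object with a `states` data.frame
#'   containing `time_d` columns per analyte).
#' @param observed a [process_record()].
#' @param analytes analytes to score (default: all present in both).
#' @return data.frame(analyte, sse, r2, log_sse).
#' @export
evaluate_twin <- function(result, observed,
                          analytes = NULL) {
  st <- result$states
  if (is.null(analytes)) {
    analytes <- intersect(unique(observed$samples$analyte), names(st))
  }
  do.call(rbind, lapply(analytes, function(a) {
    obs <- record_series(observed, a)
    obs <- obs[obs$time_d <= max(st$time_d) + 1e-9, ]
    sim <- stats::approx(st$time_d, st[[a]], xout = obs$time_d,
                         rule = 2)$y
    sse <- sum((sim - obs$value)^2)
    sstot <- sum((obs$value - mean(obs$value))^2)
    data.frame(analyte = a, sse = sse,
               r2 = if (sstot > 0) 1 - sse / sstot else NA_real_,
               log_sse = log(sse))
  }))
}
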