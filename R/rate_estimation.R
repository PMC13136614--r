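#' Volume-correct a concentration series into pseudo-concentrations
#'
#' Removes the concentration steps caused by bolus feed additions (dilution
#' plus added mass) from a measured analyte series, leaving a series whose
#' variation reflects cellular exchange only. Each feed event's step is
#' computed from the measured value at the preceding sampling time with that
#' day's boluses applied in stream order, so the raw series can be
#' reconstructed exactly from the pseudo series plus the event log.
#'
#' Sampling losses remove volume at the current concentration and therefore
#' produce no concentration step.
#'
#' @param record a [process_record()].
#' @param analyte analyte name (a concentration-type analyte or `"VCD"`).
#' @return object of class `pseudo_series`: `times` (d), `values`
#'   (pseudo-concentrations), `raw` (measured values), `events`
#'   (data.frame time, delta: the concentration step attributed to each
#'   feed time), `analyte`, `batch`.
#' @export
volume_correct <- function(record, analyte) {
  s <- record_series(record, analyte)
  streams <- unique(record$feeds$stream)
  known <- unique(record$compositions$stream)
  missing <- setdiff(streams, known)
  if (length(missing)) {
    stop(sprintf("no composition for fed stream(s): %s",
                 paste(missing, collapse = ", ")))
  }
  n <- nrow(s)
  deltas <- data.frame(time = numeric(), delta = numeric())
  pseudo <- s$value
  cum <- 0
  for (i in seq_len(n)) {
    if (i > 1) pseudo[i] <- s$value[i] - cum
    t_i <- s$time_d[i]
    evs <- record$feeds[record$feeds$time_d == t_i, ]
    if (nrow(evs)) {
      evs <- evs[order(evs$stream), ]
      v <- record_volume(record, t_i, when = "pre") -
        record$sample_volume
      conc <- s$value[i]
      d_ev <- 0
      for (j in seq_len(nrow(evs))) {
        cin <- feed_concentration(record, evs$stream[j], analyte)
        step <- (cin - conc) * evs$volume_ml[j] / (v + evs$volume_ml[j])
        conc <- conc + step
        v <- v + evs$volume_ml[j]
        d_ev <- d_ev + step
      }
      cum <- cum + d_ev
      # events fire just after the (pre-feed) sample at t_i
      deltas <- rbind(deltas, data.frame(time = t_i + 1e-6, delta = d_ev))
    }
  }
  structure(list(times = s$time_d, values = pseudo, raw = s$value,
                 events = deltas, analyte = analyte,
                 batch = record$batch_id),
            class = "pseudo_series")
}

#' Reconstruct raw concentrations from a pseudo series
#'
#' Inverse of [volume_correct()] on the sampling grid: adds the cumulative
#' event steps back. At a time equal to an event time the post-event value
#' is returned.
#'
#' @param pseudo_values pseudo-concentration values at `times`.
#' @param events event table (`time`, `delta`) as stored in a
#'   `pseudo_series` or `basis_fit`.
#' @param times query times (d).
#' @return raw concentration values.
#' @export
apply_event_steps <- function(pseudo_values, events, times) {
  cum <- vapply(times, function(t) {
    sum(events$delta[events$time <= t])
  }, numeric(1))
  pseudo_values + cum
}

#' Evaluate a logistic-basis curve (with linear trend)
#'
#' Curve parameters are `c(A_1, m_1, s_1, ..., A_k, m_k, s_k, offset,
#' trend)`: a sum of k logistic functions plus an affine trend. The trend
#' term lets derivatives approach a non-zero constant at the horizon
#' boundaries (steady consumption/production), which a bounded logistic
#' sum alone cannot represent.
#'
#' @param par curve parameter vector (length 3k + 2).
#' @param t evaluation times (d).
#' @param derivative evaluate d/dt instead.
#' @return numeric vector.
#' @export
basis_curve_eval <- function(par, t, derivative = FALSE) {
  k <- (length(par) - 2L) %/% 3L
  core <- par[seq_len(3L * k + 1L)]
  trend <- par[3L * k + 2L]
  if (derivative) {
    sigmoid_sum_deriv(core, t) + trend
  } else {
    sigmoid_sum(core, t) + trend * t
  }
}

# log-posterior factory for a k-basis logistic fit.
# theta = (A_1, m_1, ls_1, ..., A_k, m_k, ls_k, offset, trend, log_sigma);
# slopes are exp(ls) > 0 (amplitudes carry the sign).
basis_logpost <- function(times, values, k, weights = NULL) {
  R <- max(diff(range(values)), 1e-3)
  if (is.null(weights)) weights <- rep(1, length(values))
  Tmid <- mean(range(times))
  Tspan <- max(diff(range(times)), 1)
  theta_to_par <- function(theta) {
    par <- numeric(3 * k + 2)
    for (i in seq_len(k)) {
      par[3 * i - 2] <- theta[3 * i - 2]
      par[3 * i - 1] <- theta[3 * i - 1]
      par[3 * i] <- exp(theta[3 * i])
    }
    par[3 * k + 1] <- theta[3 * k + 1]
    par[3 * k + 2] <- theta[3 * k + 2]
    par
  }
  list(
    theta_to_par = theta_to_par,
    d = 3L * k + 3L,
    logpost = function(theta) {
      # quadrature noise floor (0.1% of the data range) keeps noise-free
      # series well-posed
      sigma <- sqrt(exp(2 * theta[3 * k + 3]) + (1e-3 * R)^2)
      pred <- basis_curve_eval(theta_to_par(theta), times)
      ll <- sum(stats::dnorm(values, pred, sigma * weights, log = TRUE))
      lp <- 0
      for (i in seq_len(k)) {
        lp <- lp + stats::dnorm(theta[3 * i - 2], 0, 2 * R, log = TRUE) +
          stats::dnorm(theta[3 * i - 1], Tmid, Tspan, log = TRUE) +
          stats::dnorm(theta[3 * i], log(Tspan / 8), 1, log = TRUE)
      }
      lp <- lp + stats::dnorm(theta[3 * k + 1], values[1], 2 * R,
                              log = TRUE) +
        stats::dnorm(theta[3 * k + 2], 0, 2 * R / Tspan, log = TRUE) +
        stats::dnorm(theta[3 * k + 3], log(0.05 * R), 2, log = TRUE)
      out <- ll + lp
      if (!is.finite(out)) -1e12 else out
    })
}

# affine-invariant ensemble ("stretch move") sampler; walkers initialise
# from the Laplace covariance when available so the ensemble starts near
# its equilibrium dispersion
stretch_sampler <- function(logpost, theta0, n_walkers, n_steps, a = 2,
                            cov_chol = NULL) {
  d <- length(theta0)
  if (is.null(cov_chol)) {
    walkers <- matrix(rep(theta0, each = n_walkers), n_walkers, d) +
      matrix(stats::rnorm(n_walkers * d, 0, 1e-3 * (abs(theta0) + 0.05)),
             n_walkers, d, byrow = TRUE)
  } else {
    walkers <- matrix(rep(theta0, each = n_walkers), n_walkers, d) +
      matrix(stats::rnorm(n_walkers * d), n_walkers, d) %*% cov_chol
  }
  lp <- apply(walkers, 1, logpost)
  chain <- array(NA_real_, c(n_steps, n_walkers, d))
  for (s in seq_len(n_steps)) {
    for (w in seq_len(n_walkers)) {
      other <- sample(seq_len(n_walkers)[-w], 1)
      z <- ((a - 1) * stats::runif(1) + 1)^2 / a
      prop <- walkers[other, ] + z * (walkers[w, ] - walkers[other, ])
      lp_prop <- logpost(prop)
      if (log(stats::runif(1)) < (d - 1) * log(z) + lp_prop - lp[w]) {
        walkers[w, ] <- prop
        lp[w] <- lp_prop
      }
    }
    chain[s, , ] <- walkers
  }
  chain
}

#' Fit logistic-basis models to a pseudo-concentration series
#'
#' Fits linear combinations of 1..`max_basis` logistic functions (plus a
#' linear trend) by MAP (multi-start BFGS) under weakly informative,
#' data-scaled priors, ranks model orders by a Laplace approximation of the
#' log evidence, and draws a posterior sample with an affine-invariant
#' ensemble MCMC sampler. The reported `n_basis` prefers a larger model
#' only when it gains more than 1 nat of evidence; the posterior draws are
#' evidence-weighted across model orders (Bayesian model averaging), so
#' that rate uncertainty reflects model-order uncertainty as well. When
#' the series carries raw measurement values, the observation noise is
#' proportional to the raw magnitude (multiplicative assay error
#' propagated into pseudo-concentration space).
#'
#' @param series a `pseudo_series` from [volume_correct()] (or any list with
#'   `times`, `values`, optionally `events` and `raw`).
#' @param max_basis largest number of logistic basis functions to consider.
#' @param n_draws posterior draws to keep.
#' @param seed RNG seed for the sampler.
#' @param n_steps MCMC steps (half discarded as burn-in).
#' @return object of class `basis_fit`: `n_basis`, `map` (curve parameters
#'   for [basis_curve_eval()]), `draws` (n_draws x params matrix, curve
#'   scale), `log_evidence` (per model order), `sigma`, `series`.
#' @export
fit_basis <- function(series, max_basis = 3, n_draws = 100, seed = 1,
                      n_steps = 400) {
  times <- series$times
  values <- series$values
  if (length(times) < 4) stop("need at least 4 time points")
  stopifnot(max_basis >= 1)
  R <- max(diff(range(values)), 1e-3)
  Tspan <- max(diff(range(times)), 1)
  weights <- NULL
  if (!is.null(series$raw)) {
    w <- pmax(abs(series$raw), 0.05 * max(abs(series$raw)))
    weights <- w / mean(w)
  }
  fits <- list()
  log_ev <- numeric(max_basis)
  with_seed(seed, {
    for (k in seq_len(max_basis)) {
      lpf <- basis_logpost(times, values, k, weights)
      starts <- lapply(seq_len(8 + 2 * k), function(s) {
        mids <- stats::quantile(times, probs = (seq_len(k) - 0.5) / k) +
          stats::rnorm(k, 0, Tspan / 8)
        th <- numeric(lpf$d)
        for (i in seq_len(k)) {
          th[3 * i - 2] <- stats::rnorm(1, (values[length(values)] -
                                              values[1]) / k, R / 4)
          th[3 * i - 1] <- mids[i]
          th[3 * i] <- log(Tspan / 8) + stats::rnorm(1, 0, 0.8)
        }
        th[3 * k + 1] <- values[1]
        th[3 * k + 2] <- 0
        th[3 * k + 3] <- log(0.05 * R)
        th
      })
      opts <- lapply(starts, function(th) {
        stats::optim(th, function(x) -lpf$logpost(x), method = "BFGS",
                     control = list(maxit = 300))
      })
      best <- opts[[which.min(vapply(opts, `[[`, numeric(1), "value"))]]
      H <- stats::optimHess(best$par, function(x) -lpf$logpost(x))
      ldet <- determinant(H, logarithm = TRUE)
      log_ev[k] <- if (ldet$sign > 0) {
        -best$value + lpf$d / 2 * log(2 * pi) -
          0.5 * as.numeric(ldet$modulus)
      } else -Inf
      cc <- try({
        Hs <- (H + t(H)) / 2
        ev <- eigen(Hs, symmetric = TRUE)
        lam <- pmax(ev$values, max(ev$values) * 1e-10)
        # chol of H^-1 via the eigendecomposition
        t(ev$vectors %*% diag(1 / sqrt(lam), length(lam)))
      }, silent = TRUE)
      if (inherits(cc, "try-error")) cc <- NULL
      fits[[k]] <- list(theta = best$par, lpf = lpf, value = -best$value,
                        cov_chol = cc)
    }
    k_sel <- 1L
    if (max_basis > 1) {
      for (k in 2:max_basis) {
        if (is.finite(log_ev[k]) && log_ev[k] > log_ev[k_sel] + 1) k_sel <- k
      }
    }
    # evidence-weighted draw allocation across model orders (orders more
    # than 6 nats below the best contribute nothing)
    wts <- exp(log_ev - max(log_ev[is.finite(log_ev)]))
    wts[!is.finite(wts)] <- 0
    n_per <- round(n_draws * wts / sum(wts))
    n_per[which.max(wts)] <- n_per[which.max(wts)] +
      (n_draws - sum(n_per))
    draw_list <- list()
    for (k in which(n_per > 0)) {
      f <- fits[[k]]
      n_walkers <- max(2 * f$lpf$d + 2, 16)
      chain <- stretch_sampler(f$lpf$logpost, f$theta, n_walkers, n_steps,
                               cov_chol = f$cov_chol)
      keep <- chain[seq(n_steps %/% 2 + 1, n_steps), , , drop = FALSE]
      flat <- matrix(keep, ncol = f$lpf$d)
      idx <- sample(nrow(flat), n_per[k], replace = nrow(flat) < n_per[k])
      th <- flat[idx, , drop = FALSE]
      pars <- t(apply(th, 1, f$lpf$theta_to_par))
      # pad to the widest parameterisation with inert components
      draw_list[[length(draw_list) + 1L]] <- pars
    }
    width <- max(vapply(draw_list, ncol, 1L))
    draws <- do.call(rbind, lapply(draw_list, function(m) {
      if (ncol(m) == width) return(m)
      k_m <- (ncol(m) - 2L) %/% 3L
      k_w <- (width - 2L) %/% 3L
      pad <- matrix(rep(c(0, 0, 1), k_w - k_m), nrow(m),
                    3 * (k_w - k_m), byrow = TRUE)
      cbind(m[, seq_len(3 * k_m), drop = FALSE], pad,
            m[, 3 * k_m + 1:2, drop = FALSE])
    }))
    f_sel <- fits[[k_sel]]
    structure(list(
      n_basis = k_sel,
      map = f_sel$lpf$theta_to_par(f_sel$theta),
      sigma = exp(f_sel$theta[f_sel$lpf$d]),
      draws = draws,
      log_evidence = log_ev,
      series = series), class = "basis_fit")
  })
}

#' @export
print.basis_fit <- function(x, ...) {
  cat(sprintf("<basis_fit '%s'/'%s': n_basis=%d, sigma=%.4g, logZ=%s>\n",
              x$series$batch %||% "?", x$series$analyte %||% "?",
              x$n_basis, x$sigma,
              paste(round(x$log_evidence, 1), collapse = "/")))
  invisible(x)
}

#' Evaluate posterior pseudo-concentration curves
#'
#' @param fit a [fit_basis()] result.
#' @param times evaluation times (d).
#' @param derivative evaluate the analytic time derivative instead.
#' @return matrix (draws x times).
#' @export
basis_curves <- function(fit, times, derivative = FALSE) {
  t(apply(fit$draws, 1, basis_curve_eval, t = times,
          derivative = derivative))
}

#' Build a rate ensemble from a basis fit
#'
#' Each trajectory is the analytic time derivative of one posterior
#' pseudo-concentration curve divided by the paired viable-cell-density
#' trajectory, giving cell-specific rates (consumption negative, production
#' positive). VCD may be a constant, a function of time, an interpolatable
#' series, or a VCD `basis_fit` (index-matched pairing of posterior draws).
#'
#' @param fit a [fit_basis()] result for the analyte.
#' @param vcd viable cell density: scalar, function(t), data.frame
#'   (time_d, value), or a `basis_fit` of VCD.
#' @param times evaluation times (d).
#' @param n_traj trajectories to generate.
#' @param seed seed for draw selection.
#' @return object of class `rate_ensemble`: `times`, `trajectories`
#'   (n_traj x n_times), `mean`, `p5`, `p95`, `analyte`, `batch`.
#' @export
sample_rates <- function(fit, vcd, times, n_traj = 100, seed = 1) {
  lo <- min(fit$series$times); hi <- max(fit$series$times)
  if (any(times < lo - 1e-9 | times > hi + 1e-9)) {
    stop("requested times outside the fitted horizon")
  }
  with_seed(seed, {
    idx <- sample(nrow(fit$draws), n_traj, replace = nrow(fit$draws) < n_traj)
    dcurves <- basis_curves(fit, times, derivative = TRUE)[idx, ,
                                                           drop = FALSE]
    vmat <- vcd_matrix(vcd, times, n_traj)
    if (any(vmat <= 0)) stop("VCD <= 0 at a requested time")
    rate_ensemble(times, dcurves / vmat,
                  analyte = fit$series$analyte, batch = fit$series$batch)
  })
}

vcd_matrix <- function(vcd, times, n_traj) {
  if (inherits(vcd, "basis_fit")) {
    idx <- sample(nrow(vcd$draws), n_traj,
                  replace = nrow(vcd$draws) < n_traj)
    basis_curves(vcd, times)[idx, , drop = FALSE]
  } else if (is.function(vcd)) {
    matrix(rep(vcd(times), each = n_traj), n_traj)
  } else if (is.data.frame(vcd)) {
    f <- stats::approxfun(vcd$time_d, vcd$value, rule = 2)
    matrix(rep(f(times), each = n_traj), n_traj)
  } else if (is.numeric(vcd) && length(vcd) == 1) {
    matrix(vcd, n_traj, length(times))
  } else stop("unsupported vcd specification")
}

#' Construct a rate ensemble
#'
#' @param times times (d).
#' @param trajectories n_traj x n_times matrix of specific rates.
#' @param analyte,batch ids.
#' @return `rate_ensemble` with per-time mean and 5th/95th percentiles.
#' @export
rate_ensemble <- function(times, trajectories, analyte = NA, batch = NA) {
  stopifnot(ncol(trajectories) == length(times))
  structure(list(times = times, trajectories = trajectories,
                 mean = colMeans(trajectories),
                 p5 = apply(trajectories, 2, stats::quantile, 0.05),
                 p95 = apply(trajectories, 2, stats::quantile, 0.95),
                 analyte = analyte, batch = batch),
            class = "rate_ensemble")
}

#' @export
print.rate_ensemble <- function(x, ...) {
  cat(sprintf("<rate_ensemble '%s'/'%s': %d trajectories x %d times [%g, %g] d>\n",
              x$batch, x$analyte, nrow(x$trajectories), length(x$times),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Back-propagate a posterior fit to raw concentrations
#'
#' Reapplies the feed-event concentration steps to the posterior
#' pseudo-concentration curves, reconstructing the measured concentration
#' scale at arbitrary times (post-event value at a tie).
#'
#' @param fit a [fit_basis()] result carrying its `pseudo_series`.
#' @param times query times within the fitted horizon.
#' @return matrix (draws x times) of reconstructed concentrations.
#' @export
reconstruct_concentrations <- function(fit, times) {
  lo <- min(fit$series$times); hi <- max(fit$series$times)
  if (any(times < lo - 1e-9 | times > hi + 1e-9)) {
    stop("requested times outside the fitted horizon")
  }
  curves <- basis_curves(fit, times)
  ev <- fit$series$events
  if (is.null(ev) || !nrow(ev)) return(curves)
  sweep(curves, 2, apply_event_steps(numeric(length(times)), ev, times),
        "+")
}

#' Estimate net specific growth rate from VCD measurements
#'
#' Applies the basis-fit machinery to log(VCD); the analytic derivative of
#' the fitted log-curve is the net specific growth rate, so no VCD division
#' is needed.
#'
#' @param record a [process_record()].
#' @param max_basis,n_draws,seed,n_steps passed to [fit_basis()].
#' @param n_traj trajectories in the returned ensemble.
#' @param times evaluation times; defaults to the sampling grid.
#' @return list with `fit` (basis fit of log VCD) and `mu` (a
#'   `rate_ensemble` of growth rate, 1/d).
#' @export
estimate_growth <- function(record, max_basis = 3, n_draws = 200,
                            seed = 1, n_steps = 400, n_traj = 200,
                            times = NULL) {
  s <- record_series(record, "VCD")
  if (any(s$value <= 0)) stop("non-positive VCD measurement")
  series <- structure(list(times = s$time_d, values = log(s$value),
                           events = NULL, analyte = "VCD",
                           batch = record$batch_id),
                      class = "pseudo_series")
  fit <- fit_basis(series, max_basis = max_basis, n_draws = n_draws,
                   seed = seed, n_steps = n_steps)
  if (is.null(times)) times <- s$time_d
  with_seed(seed + 1L, {
    idx <- sample(nrow(fit$draws), n_traj,
                  replace = nrow(fit$draws) < n_traj)
    mu <- rate_ensemble(times,
                        basis_curves(fit, times,
                                     derivative = TRUE)[idx, , drop = FALSE],
                        analyte = "mu", batch = record$batch_id)
  })
  list(fit = fit, mu = mu)
}

#' Estimate specific-rate ensembles for a set of analytes
#'
#' Convenience driver: volume-correct, fit, and sample rate ensembles for
#' each analyte of a record, pairing every analyte with the same VCD fit.
#'
#' @param record a [process_record()].
#' @param analytes analyte names (default: all 24 concentration analytes).
#' @param times evaluation times (default sampling grid).
#' @param n_traj trajectories per ensemble.
#' @param max_basis,seed,n_steps passed to [fit_basis()].
#' @return named list of `rate_ensemble`s, plus attribute `"vcd_fit"`.
#' @export
estimate_rates <- function(record,
                           analytes = setdiff(chotwin_analytes()$all, "VCD"),
                           times = NULL, n_traj = 100, max_basis = 3,
                           seed = 1, n_steps = 400) {
  svcd <- record_series(record, "VCD")
  vfit <- fit_basis(structure(list(times = svcd$time_d,
                                   values = log(svcd$value), events = NULL,
                                   analyte = "VCD",
                                   batch = record$batch_id),
                              class = "pseudo_series"),
                    max_basis = max_basis, seed = seed, n_steps = n_steps)
  if (is.null(times)) times <- svcd$time_d
  out <- lapply(analytes, function(a) {
    ps <- volume_correct(record, a)
    fit <- fit_basis(ps, max_basis = max_basis, seed = seed + 1L,
                     n_steps = n_steps)
    ens <- with_seed(seed + 2L, {
      n_av <- nrow(fit$draws)
      idx <- sample(n_av, n_traj, replace = n_av < n_traj)
      dc <- basis_curves(fit, times, derivative = TRUE)[idx, , drop = FALSE]
      vidx <- sample(nrow(vfit$draws), n_traj,
                     replace = nrow(vfit$draws) < n_traj)
      vmat <- exp(basis_curves(vfit, times)[vidx, , drop = FALSE])
      rate_ensemble(times, dc / vmat, analyte = a, batch = record$batch_id)
    })
    attr(ens, "fit") <- fit
    ens
  })
  names(out) <- analytes
  attr(out, "vcd_fit") <- vfit
  out
}
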