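#' Window-PCA loading targets from exchange-rate trajectories
#'
#' Discretises rate trajectories into fixed windows and, per media group and
#' window, runs a PCA across the batches of that group on the window-mean
#' exchange-rate vectors. The smallest number of components reaching the
#' variance threshold (capped at `max_pc`) is retained; the orthonormal
#' loadings are the regression targets for the loading model.
#'
#' @param rates long data.frame with columns `batch`, `group`, `time_d`,
#'   `analyte`, `rate` (ensemble-mean specific rates).
#' @param window window width (d).
#' @param var_threshold cumulative explained-variance target.
#' @param max_pc maximum retained components.
#' @return object of class `loading_targets`: list of entries with `group`,
#'   `window` (c(t0, t1)), `loadings` (metabolites x k), `explained`,
#'   `k`, `batch_features` (batches x metabolites window means),
#'   `degenerate` flag; plus attribute `analytes`.
#' @export
window_pca <- function(rates, window = 0.5, var_threshold = 0.90,
                       max_pc = 5) {
  analytes <- sort(unique(rates$analyte))
  out <- list()
  for (g in sort(unique(rates$group))) {
    rg <- rates[rates$group == g, ]
    t0s <- seq(min(rg$time_d),
               max(min(rg$time_d), max(rg$time_d) - 1e-9), by = window)
    for (t0 in t0s) {
      rw <- rg[rg$time_d >= t0 & rg$time_d < t0 + window, ]
      if (!nrow(rw)) next
      M <- tapply(rw$rate, list(rw$batch, rw$analyte), mean)
      M <- M[, analytes, drop = FALSE]
      if (nrow(M) < 2 || anyNA(M)) next
      cm <- colMeans(M)
      Mc <- sweep(M, 2, cm)
      sv <- svd(Mc)
      ev <- sv$d^2 / max(sum(sv$d^2), 1e-300)
      if (sum(sv$d^2) < 1e-20) {
        # constant rates across batches: flagged degenerate window
        warning(sprintf("zero-variance window [%g,%g) in group %s", t0,
                        t0 + window, g))
        load <- matrix(0, length(analytes), 1,
                       dimnames = list(analytes, NULL))
        load[1, 1] <- 1
        out[[length(out) + 1L]] <- list(
          group = g, window = c(t0, t0 + window), loadings = load,
          explained = 1, k = 1L, center = cm, batch_features = M,
          degenerate = TRUE)
        next
      }
      k <- min(which(cumsum(ev) >= var_threshold - 1e-12), max_pc)
      if (var_threshold <= 0) k <- 1L
      k <- min(k, max_pc, ncol(sv$v))
      load <- sv$v[, seq_len(k), drop = FALSE]
      rownames(load) <- analytes
      out[[length(out) + 1L]] <- list(
        group = g, window = c(t0, t0 + window), loadings = load,
        explained = ev[seq_len(k)], k = as.integer(k), center = cm,
        batch_features = M, degenerate = FALSE)
    }
  }
  structure(out, class = "loading_targets", analytes = analytes)
}

#' Train per-component loading regressors
#'
#' One small neural regressor per principal-component index (1..`max_pc`)
#' maps standardized exchange-rate features to standardized loading
#' vectors. Windows lacking a component contribute zero-filled targets so
#' the output dimensionality is fixed. Hyperparameters (hidden units,
#' weight decay) are selected on a held-out split by RMSE within a small
#' seeded grid.
#'
#' @param targets a `loading_targets` from [window_pca()].
#' @param feature_set `"ALL"` (all analytes) or `"FLEX"` (the five FLEX
#'   metabolites plus growth/VCD when present).
#' @param max_pc output components.
#' @param hp_grid data.frame(size, decay) of candidate hyperparameters.
#' @param seed RNG seed (nnet init and splits).
#' @param maxit nnet iteration budget.
#' @return object of class `loading_model`.
#' @export
train_loading_model <- function(targets, feature_set = c("ALL", "FLEX"),
                                max_pc = 5,
                                hp_grid = data.frame(
                                  size = c(4, 8, 8),
                                  decay = c(1e-2, 1e-2, 1e-3)),
                                seed = 1, maxit = 300) {
  feature_set <- match.arg(feature_set)
  analytes <- attr(targets, "analytes")
  feat_cols <- if (feature_set == "ALL") analytes else
    intersect(c("Glc", "Lac", "Gln", "Glu", "NH4", "VCD", "growth"),
              analytes)
  if (!length(feat_cols)) stop("no usable feature columns")
  X <- list(); Y <- lapply(seq_len(max_pc), function(i) list())
  for (w in targets) {
    bf <- w$batch_features
    for (b in rownames(bf)) {
      X[[length(X) + 1L]] <- bf[b, feat_cols]
      for (j in seq_len(max_pc)) {
        Y[[j]][[length(X)]] <- if (j <= w$k) w$loadings[, j] else
          rep(0, length(analytes))
      }
    }
  }
  if (!length(X)) stop("empty training set")
  X <- do.call(rbind, X)
  xs <- scale_fit(X)
  Xs <- scale_apply(xs, X)
  with_seed(seed, {
    models <- lapply(seq_len(max_pc), function(j) {
      Yj <- do.call(rbind, Y[[j]])
      ys <- scale_fit(Yj)
      Yjs <- scale_apply(ys, Yj)
      n <- nrow(Xs)
      val <- sample(n, max(1, round(0.2 * n)))
      tr <- setdiff(seq_len(n), val)
      cand <- lapply(seq_len(nrow(hp_grid)), function(h) {
        fit <- nnet::nnet(Xs[tr, , drop = FALSE], Yjs[tr, , drop = FALSE],
                          size = hp_grid$size[h], decay = hp_grid$decay[h],
                          linout = TRUE, maxit = maxit, trace = FALSE)
        pr <- stats::predict(fit, Xs[val, , drop = FALSE])
        list(fit = fit, rmse = sqrt(mean((pr - Yjs[val, ])^2)), h = h)
      })
      best <- cand[[which.min(vapply(cand, `[[`, numeric(1), "rmse"))]]
      # refit on everything with the winning hyperparameters
      fit <- nnet::nnet(Xs, Yjs, size = hp_grid$size[best$h],
                        decay = hp_grid$decay[best$h], linout = TRUE,
                        maxit = maxit, trace = FALSE)
      list(fit = fit, y_scaler = ys, rmse = best$rmse, hp = best$h)
    })
    structure(list(models = models, x_scaler = xs, feat_cols = feat_cols,
                   analytes = analytes, feature_set = feature_set,
                   max_pc = max_pc),
              class = "loading_model")
  })
}

#' Predict a loading matrix from exchange-rate features
#'
#' @param model a [train_loading_model()] fit.
#' @param features named numeric vector of exchange rates (must cover the
#'   model's feature columns).
#' @return metabolites x max_pc loading matrix (de-normalised).
#' @export
predict_loadings <- function(model, features) {
  x <- matrix(features[model$feat_cols], 1)
  xs <- scale_apply(model$x_scaler, x)
  L <- vapply(model$models, function(m) {
    pr <- stats::predict(m$fit, xs)
    as.numeric(pr) * m$y_scaler$sd + m$y_scaler$mean
  }, numeric(length(model$analytes)))
  rownames(L) <- model$analytes
  L
}

#' Cross-validate loading models
#'
#' Three schemes: `direct` (IID shuffle into 70:15:15 train/val/test),
#' `LOMO` (leave one media group out) and `LOBO` (leave one batch out).
#' Held-out loading predictions are scored per metabolite (R2 and SSE over
#' all held-out loading entries of that metabolite).
#'
#' @param targets a `loading_targets` from [window_pca()].
#' @param strategy validation scheme.
#' @param feature_set `"ALL"` or `"FLEX"`.
#' @param seed RNG seed.
#' @param ... passed to [train_loading_model()].
#' @return data.frame(metabolite, r2, sse, strategy).
#' @export
cross_validate <- function(targets, strategy = c("direct", "LOMO", "LOBO"),
                           feature_set = "ALL", seed = 1, ...) {
  strategy <- match.arg(strategy)
  analytes <- attr(targets, "analytes")
  groups <- unique(vapply(targets, `[[`, FUN.VALUE = targets[[1]]$group,
                          "group"))
  batches <- unique(unlist(lapply(targets, function(w) {
    rownames(w$batch_features)
  })))
  subset_targets <- function(keep_batches) {
    out <- Filter(Negate(is.null), lapply(targets, function(w) {
      keep <- intersect(rownames(w$batch_features), keep_batches)
      if (length(keep) < 1) return(NULL)
      w$batch_features <- w$batch_features[keep, , drop = FALSE]
      w
    }))
    structure(out, class = "loading_targets", analytes = analytes)
  }
  folds <- switch(strategy,
    direct = {
      with_seed(seed, {
        n <- length(batches)
        sh <- sample(batches)
        n_tr <- max(1, round(0.85 * n))   # train+val; test = remainder
        list(list(train = sh[seq_len(n_tr)],
                  test = sh[seq(n_tr + 1, n)]))
      })
    },
    LOMO = {
      if (length(groups) < 2) stop("LOMO needs at least 2 media groups")
      lapply(groups, function(g) {
        gb <- unique(unlist(lapply(targets, function(w) {
          if (w$group == g) rownames(w$batch_features) else NULL
        })))
        list(train = setdiff(batches, gb), test = gb)
      })
    },
    LOBO = lapply(batches, function(b) {
      list(train = setdiff(batches, b), test = b)
    }))
  preds <- list(); obs <- list()
  for (f in folds) {
    tr_t <- subset_targets(f$train)
    model <- train_loading_model(tr_t, feature_set = feature_set,
                                 seed = seed, ...)
    for (w in targets) {
      keep <- intersect(rownames(w$batch_features), f$test)
      for (b in keep) {
        L <- predict_loadings(model, w$batch_features[b, ])
        truth <- matrix(0, length(analytes), ncol(L))
        truth[, seq_len(w$k)] <- w$loadings
        preds[[length(preds) + 1L]] <- L
        obs[[length(obs) + 1L]] <- truth
      }
    }
  }
  P <- do.call(cbind, lapply(preds, as.vector))
  O <- do.call(cbind, lapply(obs, as.vector))
  # rows of P/O cycle over analytes within PCs
  res <- do.call(rbind, lapply(seq_along(analytes), function(i) {
    sel <- seq(i, nrow(P), by = length(analytes))
    p <- as.vector(P[sel, ]); o <- as.vector(O[sel, ])
    sse <- sum((p - o)^2)
    sst <- sum((o - mean(o))^2)
    data.frame(metabolite = analytes[i], r2 = 1 - sse / max(sst, 1e-300),
               sse = sse)
  }))
  res$strategy <- strategy
  res
}

#' Assemble one hybrid PC-dFBA linear program
#'
#' Variables are the fluxes `v`, the PCA scores and auxiliary |score|
#' variables. Constraints: mass balance, global bounds, hard bounds on the
#' measured (FLEX + growth) subset, the empirical band linking measured
#' exchange fluxes to the PCA reconstruction, and the score box. The
#' objective maximises growth while minimising the total absolute score
#' (the empirical contribution).
#'
#' @param net a [metabolic_network()].
#' @param loadings metabolites x k matrix of predicted loadings; row names
#'   are analytes, mapped to exchanges via `net$analyte_map`.
#' @param hard_bounds named list exchange id -> c(lb, ub).
#' @param band_stats named list analyte -> c(med, iqr).
#' @param RF relaxation factor scaling the IQR band half-width.
#' @param score_bounds k x 2 matrix (or c(lb, ub) recycled).
#' @param biomass_weight weight of the growth term in the objective.
#' @return object of class `hybrid_lp`.
#' @export
build_step_problem <- function(net, loadings, hard_bounds = list(),
                               band_stats = list(), RF = 1.5,
                               score_bounds = c(-100, 100),
                               biomass_weight = 1) {
  n <- ncol(net$S)
  k <- ncol(loadings)
  meas <- intersect(names(net$analyte_map),
                    names(net$analyte_map)[net$analyte_map %in%
                                             names(band_stats)])
  m <- length(meas)
  nv <- n + 2 * k
  vn <- c(colnames(net$S), paste0("score", seq_len(k)),
          paste0("abs_score", seq_len(k)))
  lb <- c(net$lb, rep(-Inf, k), rep(0, k))
  ub <- c(net$ub, rep(Inf, k), rep(Inf, k))
  if (is.matrix(score_bounds)) {
    lb[n + seq_len(k)] <- score_bounds[, 1]
    ub[n + seq_len(k)] <- score_bounds[, 2]
  } else {
    lb[n + seq_len(k)] <- score_bounds[1]
    ub[n + seq_len(k)] <- score_bounds[2]
  }
  for (r in names(hard_bounds)) {
    j <- match(r, colnames(net$S))
    if (is.na(j)) stop(sprintf("hard-bound reaction '%s' not in model", r))
    lb[j] <- hard_bounds[[r]][1]
    ub[j] <- hard_bounds[[r]][2]
  }
  Aeq <- cbind(net$S, matrix(0, nrow(net$S), 2 * k))
  beq <- rep(0, nrow(net$S))
  Ale <- NULL; ble <- NULL
  if (m > 0) {
    Se <- matrix(0, m, nv)
    Se[cbind(seq_len(m), match(meas, colnames(net$S)))] <- 1
    L <- loadings[net$analyte_map[meas], , drop = FALSE]
    med <- vapply(net$analyte_map[meas], function(a) band_stats[[a]][1],
                  numeric(1))
    iqr <- vapply(net$analyte_map[meas], function(a) band_stats[[a]][2],
                  numeric(1))
    resid <- Se
    resid[, n + seq_len(k)] <- -L
    Ale <- rbind(resid, -resid)
    ble <- c(med + RF * iqr, -(med - RF * iqr))
  }
  abs_rows <- matrix(0, 2 * k, nv)
  for (j in seq_len(k)) {
    abs_rows[j, n + j] <- 1; abs_rows[j, n + k + j] <- -1
    abs_rows[k + j, n + j] <- -1; abs_rows[k + j, n + k + j] <- -1
  }
  Ale <- rbind(Ale, abs_rows)
  ble <- c(ble, rep(0, 2 * k))
  obj <- rep(0, nv)
  obj[match(net$objective, colnames(net$S))] <- -biomass_weight
  obj[n + k + seq_len(k)] <- 1
  structure(list(obj = obj, Aeq = Aeq, beq = beq, Ale = Ale, ble = ble,
                 lb = lb, ub = ub, n = n, k = k, names = vn, net = net,
                 meas = meas, hard_bounds = hard_bounds,
                 band_stats = band_stats, RF = RF),
            class = "hybrid_lp")
}

#' Solve one PC-dFBA step
#'
#' Stage 1 solves the hybrid LP; when a previous flux vector is supplied
#' and continuity is enabled, stage 2 fixes the stage-1 objective (within a
#' relative tolerance) and minimises the squared (or absolute) flux change
#' against the previous step's solution, lexicographically.
#'
#' @param problem a [build_step_problem()] result.
#' @param prev_flux previous-step flux vector (length n) or NULL.
#' @param continuity `"qp"` (squared change), `"l1"` (absolute change) or
#'   `"none"`.
#' @param opt_tol relative tolerance for fixing the stage-1 objective.
#' @return object of class `step_solution`: `fluxes`, `scores`,
#'   `objective`, `status`, `relaxed`, `continuity_penalty`.
#' @export
solve_step <- function(problem, prev_flux = NULL,
                       continuity = c("qp", "l1", "none"),
                       opt_tol = 1e-6) {
  continuity <- match.arg(continuity)
  p <- problem
  s1 <- solve_lp(p$obj, p$Aeq, p$beq, p$Ale, p$ble, p$lb, p$ub)
  if (s1$status != "optimal") {
    return(structure(list(fluxes = NULL, scores = NULL,
                          objective = NA_real_, status = "infeasible",
                          relaxed = FALSE, continuity_penalty = NA_real_),
                     class = "step_solution"))
  }
  x <- s1$x
  penalty <- NA_real_
  if (!is.null(prev_flux) && continuity != "none") {
    fix_row <- matrix(p$obj, 1)
    fix_rhs <- s1$objective + opt_tol * (1 + abs(s1$objective))
    if (continuity == "qp") {
      s2 <- solve_moma_qp(seq_len(p$n), prev_flux, length(p$obj),
                          Aeq = p$Aeq, beq = p$beq,
                          Ale = rbind(p$Ale, fix_row),
                          ble = c(p$ble, fix_rhs),
                          lb = p$lb, ub = p$ub)
      if (s2$status == "optimal") {
        x <- s2$x
        penalty <- s2$penalty
      }
    } else {
      # L1 continuity: v = prev + d+ - d-, minimise sum(d+ + d-)
      nv <- length(p$obj); n <- p$n
      obj2 <- c(rep(0, nv), rep(1, 2 * n))
      D <- matrix(0, n, 2 * n)
      D[cbind(seq_len(n), seq_len(n))] <- -1
      D[cbind(seq_len(n), n + seq_len(n))] <- 1
      link <- cbind(diag(nv)[seq_len(n), , drop = FALSE], D)
      s2 <- solve_lp(obj2,
                     Aeq = rbind(cbind(p$Aeq, matrix(0, nrow(p$Aeq),
                                                     2 * n)), link),
                     beq = c(p$beq, prev_flux),
                     Ale = cbind(rbind(p$Ale, fix_row),
                                 matrix(0, nrow(p$Ale) + 1, 2 * n)),
                     ble = c(p$ble, fix_rhs),
                     lb = c(p$lb, rep(0, 2 * n)),
                     ub = c(p$ub, rep(Inf, 2 * n)))
      if (s2$status == "optimal") {
        x <- s2$x[seq_len(nv)]
        penalty <- sum(abs(x[seq_len(p$n)] - prev_flux))
      }
    }
  }
  structure(list(
    fluxes = stats::setNames(x[seq_len(p$n)], colnames(p$net$S)),
    scores = x[p$n + seq_len(p$k)],
    objective = sum(p$obj * x),
    biomass = x[match(p$net$objective, colnames(p$net$S))],
    status = "optimal", relaxed = FALSE,
    continuity_penalty = penalty), class = "step_solution")
}

#' Relax hard bounds to the ensemble percentile band
#'
#' When the mean-pinned hard bounds make the LP infeasible they are widened
#' to the 5th/95th percentile band of the corresponding rate distribution.
#'
#' @param problem a [build_step_problem()] result.
#' @param percentile_bounds named list exchange id -> c(p5, p95).
#' @return the problem with widened hard bounds.
#' @export
relax_hard_bounds <- function(problem, percentile_bounds) {
  p <- problem
  for (r in names(p$hard_bounds)) {
    if (!r %in% names(percentile_bounds)) next
    j <- match(r, colnames(p$net$S))
    pb <- percentile_bounds[[r]]
    p$lb[j] <- min(pb[1], p$hard_bounds[[r]][1])
    p$ub[j] <- max(pb[2], p$hard_bounds[[r]][2])
  }
  p$relaxed <- TRUE
  p
}

#' Band statistics of measured rates over the reliability intervals
#'
#' The culture duration is split at day 3 (lower MetRaC reliability before
#' day 3); per analyte and interval the median and interquartile range of
#' the ensemble rate values are computed. The boundary time belongs to the
#' second interval.
#'
#' @param ensembles named list of [rate_ensemble()]s.
#' @param split interval boundary (d).
#' @return function(analyte, t) -> c(med, iqr).
#' @export
band_statistics <- function(ensembles, split = 3) {
  pre <- list(); post <- list()
  for (a in names(ensembles)) {
    e <- ensembles[[a]]
    early <- e$trajectories[, e$times < split, drop = FALSE]
    late <- e$trajectories[, e$times >= split, drop = FALSE]
    stat <- function(x) if (length(x)) {
      c(stats::median(x), stats::IQR(x))
    } else c(0, 0)
    pre[[a]] <- stat(as.vector(early))
    post[[a]] <- stat(as.vector(late))
  }
  function(analyte, t) {
    if (t < split) pre[[analyte]] else post[[analyte]]
  }
}

#' Sequential PC-dFBA dynamic simulation
#'
#' Iterates the four-step loop over `dt` intervals: normalise the current
#' exchange-rate estimates, predict per-component loadings, solve the
#' hybrid LP (with MOMA continuity after the first step, and hard-bound
#' relaxation on infeasibility), then advance the extracellular
#' concentrations by the bioreactor mass balance.
#'
#' @param net a [metabolic_network()] whose exchanges map to analytes.
#' @param loading_model a [train_loading_model()] fit.
#' @param hard_bound_fun function(t) -> named list exchange -> c(lb, ub)
#'   (mean-pinned hard bounds for growth + FLEX exchanges).
#' @param percentile_fun function(t) -> named list exchange -> c(p5, p95)
#'   for relaxation, or NULL.
#' @param rate_feature_fun function(t, state) -> named vector of exchange
#'   rates used as loading-model features.
#' @param band_fun function(analyte, t) -> c(med, iqr), e.g. from
#'   [band_statistics()].
#' @param init named initial concentrations (g/l) incl. `VCD`.
#' @param feed_fun function(t, dt, state) -> named concentration increments
#'   for the step (feed additions minus washout), or NULL.
#' @param horizon simulation end (d).
#' @param dt step (d).
#' @param RF relaxation factor.
#' @param score_bounds passed to [build_step_problem()].
#' @param conversion flux-to-specific-rate conversion factor.
#' @param continuity continuity mode for [solve_step()].
#' @return object of class `pcdfba_result`: data.frame `states`, list
#'   `steps` (per-step solution diagnostics), `times`.
#' @export
pc_dfba_simulate <- function(net, loading_model, hard_bound_fun,
                             percentile_fun = NULL, rate_feature_fun,
                             band_fun, init, feed_fun = NULL, horizon,
                             dt = 0.1, RF = 1.5, score_bounds = c(-100, 100),
                             conversion = 1,
                             continuity = c("qp", "l1", "none")) {
  continuity <- match.arg(continuity)
  times <- seq(0, horizon, by = dt)
  state <- init
  states <- matrix(NA_real_, length(times), length(init),
                   dimnames = list(NULL, names(init)))
  steps <- vector("list", length(times) - 1)
  prev <- NULL
  amap <- net$analyte_map
  for (i in seq_along(times)) {
    states[i, ] <- state
    if (i == length(times)) break
    t <- times[i]
    feats <- rate_feature_fun(t, state)
    L <- predict_loadings(loading_model, feats)
    bstats <- lapply(stats::setNames(nm = unname(amap)), band_fun, t = t)
    prob <- build_step_problem(net, L, hard_bounds = hard_bound_fun(t),
                               band_stats = bstats, RF = RF,
                               score_bounds = score_bounds)
    sol <- solve_step(prob, prev_flux = prev, continuity = continuity)
    relaxed <- FALSE
    if (sol$status != "optimal" && !is.null(percentile_fun)) {
      prob <- relax_hard_bounds(prob, percentile_fun(t))
      sol <- solve_step(prob, prev_flux = prev, continuity = continuity)
      relaxed <- TRUE
    }
    if (sol$status != "optimal") {
      stop(sprintf("irreducibly infeasible PC-dFBA step at t = %.2f d", t))
    }
    sol$relaxed <- relaxed
    steps[[i]] <- sol
    # mass-balance update: specific rate = flux * conversion
    Xv <- state[["VCD"]]
    mu <- sol$biomass * conversion
    for (rxn in names(amap)) {
      a <- amap[[rxn]]
      if (!a %in% names(state) || a == "VCD") next
      rate <- sol$fluxes[[rxn]] * conversion
      state[[a]] <- max(state[[a]] + rate * Xv * dt, 0)
    }
    state[["VCD"]] <- Xv * (1 + mu * dt)
    if (!is.null(feed_fun)) {
      add <- feed_fun(t, dt, state)
      for (a in names(add)) state[[a]] <- max(state[[a]] + add[[a]], 0)
    }
    prev <- sol$fluxes
  }
  structure(list(times = times,
                 states = as.data.frame(cbind(time_d = times, states)),
                 steps = steps), class = "pcdfba_result")
}

#' PC-dFVA: flux variability under the hybrid constraints
#'
#' Fixes the hybrid objective at its optimum (within tolerance) and
#' minimises/maximises each exchange flux subject to all PC-dFBA
#' constraints, quantifying the remaining solution-space variability.
#'
#' @param problem a [build_step_problem()] result.
#' @param solution the corresponding [solve_step()] solution.
#' @param reactions exchanges to scan (default: all exchanges).
#' @param opt_tol relative objective tolerance.
#' @return data.frame(reaction, min, max).
#' @export
pc_dfva <- function(problem, solution,
                    reactions = exchange_reactions(problem$net),
                    opt_tol = 1e-6) {
  p <- problem
  fix_row <- matrix(p$obj, 1)
  fix_rhs <- solution$objective + opt_tol * (1 + abs(solution$objective))
  res <- t(vapply(reactions, function(r) {
    j <- match(r, colnames(p$net$S))
    o <- rep(0, length(p$obj)); o[j] <- 1
    lo <- solve_lp(o, p$Aeq, p$beq, rbind(p$Ale, fix_row),
                   c(p$ble, fix_rhs), p$lb, p$ub)
    hi <- solve_lp(-o, p$Aeq, p$beq, rbind(p$Ale, fix_row),
                   c(p$ble, fix_rhs), p$lb, p$ub)
    c(if (lo$status == "optimal") lo$x[j] else NA_real_,
      if (hi$status == "optimal") hi$x[j] else NA_real_)
  }, numeric(2)))
  data.frame(reaction = reactions, min = res[, 1], max = res[, 2],
             row.names = NULL)
}
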