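#' Fit the 4-sigmoid baseline growth-rate interpolator
#'
#' Least-squares fit of a sum of `n_sigmoids` logistic functions (plus
#' offset) to pooled mean specific growth rates across training batches.
#' The baseline captures average growth behaviour independent of batch
#' features; the deviation network corrects it.
#'
#' @param mu_data data.frame with columns `time_d` and `mu` (1/d), pooled
#'   over training batches; or a list of `rate_ensemble`s of growth rate.
#' @param n_sigmoids number of logistic terms.
#' @param n_starts seeded multi-starts.
#' @param seed RNG seed.
#' @return object of class `baseline_model`: `par` ([sigmoid_sum()] layout),
#'   `rmse`, `fun`.
#' @export
fit_baseline <- function(mu_data, n_sigmoids = 4, n_starts = 24,
                         seed = 1) {
  if (is.list(mu_data) && !is.data.frame(mu_data) &&
      all(vapply(mu_data, inherits, logical(1), "rate_ensemble"))) {
    if (length(mu_data) < 2) {
      warning("baseline interpolates a single batch")
    }
    mu_data <- do.call(rbind, lapply(mu_data, function(e) {
      data.frame(time_d = e$times, mu = e$mean)
    }))
  }
  t <- mu_data$time_d; y <- mu_data$mu
  Tspan <- max(diff(range(t)), 1)
  R <- max(diff(range(y)), 1e-4)
  sse <- function(par) sum((sigmoid_sum(par, t) - y)^2)
  with_seed(seed, {
    fits <- lapply(seq_len(n_starts), function(s) {
      par0 <- numeric(3 * n_sigmoids + 1)
      mids <- stats::quantile(t, (seq_len(n_sigmoids) - 0.5) / n_sigmoids)
      for (i in seq_len(n_sigmoids)) {
        par0[3 * i - 2] <- stats::rnorm(1, 0, R)
        par0[3 * i - 1] <- mids[i] + stats::rnorm(1, 0, Tspan / 10)
        par0[3 * i] <- sample(c(-1, 1), 1) *
          exp(log(Tspan / 10) + stats::rnorm(1, 0, 0.4))
      }
      par0[3 * n_sigmoids + 1] <- mean(y)
      f <- stats::optim(par0, sse, method = "BFGS",
                        control = list(maxit = 500))
      # Levenberg-Marquardt polish sharpens each least-squares optimum
      lm <- try(suppressWarnings(minpack.lm::nls.lm(
        f$par, fn = function(par) sigmoid_sum(par, t) - y,
        control = minpack.lm::nls.lm.control(maxiter = 300))),
        silent = TRUE)
      if (!inherits(lm, "try-error") && sum(lm$fvec^2) < f$value) {
        list(par = lm$par, value = sum(lm$fvec^2))
      } else f
    })
    best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
    if (any(!is.finite(best$par))) stop("degenerate baseline fit")
    structure(list(par = best$par,
                   rmse = sqrt(best$value / length(y)),
                   fun = function(tt) sigmoid_sum(best$par, tt)),
              class = "baseline_model")
  })
}

#' Trajectory representativeness weights
#'
#' Upweights trajectories whose mean growth rate is near the batch mean and
#' downweights outliers: `W_n` proportional to
#' `1 / (|mean(mu_n) - grand mean| + eps)`, normalised to sum to one.
#'
#' @param mu_trajectories n_traj x n_times matrix of growth-rate draws.
#' @param eps regulariser.
#' @return numeric weights summing to 1.
#' @export
trajectory_weights <- function(mu_trajectories, eps = 1e-6) {
  m <- rowMeans(mu_trajectories)
  w <- 1 / (abs(m - mean(m)) + eps)
  w / sum(w)
}

#' Linear decreasing time weights
#'
#' `w(t) = (T_end - t) / T_end`: early time points dominate because early
#' growth strongly determines later productivity.
#'
#' @param times time points (d).
#' @param T_end batch end time (d).
#' @return numeric weights.
#' @export
time_weights <- function(times, T_end) {
  stopifnot(all(times <= T_end))
  (T_end - times) / T_end
}

#' Composite growth-rate training loss
#'
#' Three terms: (1) trajectory- and time-weighted MSE between predicted and
#' target growth rates; (2) absolute difference of the time-summed
#' trajectory means (end-point consistency); (3) smoothness, the summed
#' absolute second difference of each predicted trajectory (mean over
#' trajectories).
#'
#' @param predictions,targets n_traj x n_times matrices.
#' @param w_traj trajectory weights (sum 1); defaults to uniform.
#' @param w_time time weights; defaults to 1.
#' @param dt time step (retained for interface symmetry; the discrete
#'   second difference is used as the curvature integral).
#' @return list of class `loss_components`: `weighted_mse`,
#'   `mean_matching`, `smoothness`, `total`.
#' @export
compute_loss <- function(predictions, targets, w_traj = NULL, w_time = NULL,
                         dt = 1) {
  if (any(!is.finite(predictions)) || any(!is.finite(targets))) {
    stop("non-finite values in loss inputs")
  }
  stopifnot(all(dim(predictions) == dim(targets)))
  nt <- ncol(predictions)
  n <- nrow(predictions)
  if (is.null(w_traj)) w_traj <- rep(1 / n, n)
  if (is.null(w_time)) w_time <- rep(1, nt)
  err2 <- (predictions - targets)^2
  term1 <- sum(w_traj * (err2 %*% w_time) / nt)
  term2 <- abs(sum(colMeans(predictions) - colMeans(targets)))
  term3 <- if (nt >= 3) {
    d2 <- predictions[, -c(1, 2), drop = FALSE] -
      2 * predictions[, -c(1, nt), drop = FALSE] +
      predictions[, -c(nt - 1, nt), drop = FALSE]
    sum(abs(d2)) / n
  } else 0
  structure(list(weighted_mse = term1, mean_matching = term2,
                 smoothness = term3,
                 total = term1 + term2 + term3),
            class = "loss_components")
}

#' One step of the biomass/biomaterial recurrence
#'
#' First-order update of `dX/dt = mu X` and the cumulative biomaterial
#' integral: `Xv' = Xv (1 + mu dt)`, `gamma' = gamma + Xv dt` (the
#' biomaterial accrues from the pre-step viable density).
#'
#' @param Xv_prev viable cell density (1e6 cells/ml).
#' @param mu_prev growth rate over the step (1/d).
#' @param gamma_prev biomaterial (1e6 cells.d/ml).
#' @param dt step (d).
#' @return c(Xv, gamma).
#' @export
recurrence_step <- function(Xv_prev, mu_prev, gamma_prev, dt) {
  stopifnot(dt > 0)
  c(Xv = Xv_prev * (1 + mu_prev * dt),
    gamma = gamma_prev + Xv_prev * dt)
}

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

#' Initialise the deviation network
#'
#' Dense network with a fixed reference layout (hidden widths 64, 64, 64,
#' 16, 8 and a single linear output), GeLU activations, per-layer layer
#' normalisation with learnable scale/shift, and dropout between hidden
#' layers.
#'
#' @param n_features input width (2k+3; 45 for the 21-metabolite panel).
#' @param widths layer widths.
#' @param dropout dropout rate.
#' @param seed initialisation seed.
#' @return object of class `deviation_network`.
#' @export
init_deviation_network <- function(n_features,
                                   widths = c(64, 64, 64, 16, 8, 1),
                                   dropout = 0.1, seed = 1) {
  dims <- c(n_features, widths)
  with_seed(seed, {
    layers <- lapply(seq_len(length(dims) - 1), function(l) {
      fan_in <- dims[l]
      list(W = matrix(stats::rnorm(dims[l] * dims[l + 1], 0,
                                   sqrt(2 / fan_in)),
                      dims[l], dims[l + 1]),
           b = rep(0, dims[l + 1]),
           g = rep(1, dims[l + 1]),   # layer-norm scale
           s = rep(0, dims[l + 1]))   # layer-norm shift
    })
    structure(list(layers = layers, dropout = dropout,
                   n_features = n_features, widths = widths),
              class = "deviation_network")
  })
}

# forward pass; X is samples x features. Returns y and a cache for backprop.
mlp_forward <- function(net, X, training = FALSE) {
  L <- length(net$layers)
  cache <- vector("list", L)
  A <- X
  for (l in seq_len(L)) {
    ly <- net$layers[[l]]
    Z <- A %*% ly$W + matrix(ly$b, nrow(A), length(ly$b), byrow = TRUE)
    if (l < L) {
      mu <- rowMeans(Z)
      v <- rowMeans((Z - mu)^2)
      sd <- sqrt(v + 1e-5)
      Zh <- (Z - mu) / sd
      Zn <- sweep(sweep(Zh, 2, ly$g, "*"), 2, ly$s, "+")
      H <- gelu(Zn)
      if (training && net$dropout > 0) {
        mask <- matrix(stats::rbinom(length(H), 1, 1 - net$dropout),
                       nrow(H)) / (1 - net$dropout)
        Hd <- H * mask
      } else {
        mask <- NULL
        Hd <- H
      }
      cache[[l]] <- list(A = A, Z = Z, Zh = Zh, Zn = Zn, sd = sd,
                         mask = mask)
      A <- Hd
    } else {
      cache[[l]] <- list(A = A)
      A <- Z
    }
  }
  list(y = A[, 1], cache = cache)
}

# backprop; dy is the gradient of the loss wrt the scalar output per sample.
mlp_backward <- function(net, cache, dy) {
  L <- length(net$layers)
  grads <- vector("list", L)
  dA <- matrix(dy, ncol = 1)
  for (l in rev(seq_len(L))) {
    ly <- net$layers[[l]]
    cc <- cache[[l]]
    if (l < L) {
      if (!is.null(cc$mask)) dA <- dA * cc$mask
      dZn <- dA * gelu_grad(cc$Zn)
      dg <- colSums(dZn * cc$Zh)
      ds <- colSums(dZn)
      dZh <- sweep(dZn, 2, ly$g, "*")
      # layer-norm backward (per row over n features)
      m <- ncol(dZh)
      row_dot <- rowSums(dZh * cc$Zh)
      row_sum <- rowSums(dZh)
      dZ <- (dZh - row_sum / m - cc$Zh * row_dot / m) / cc$sd
    } else {
      dZ <- dA
      dg <- NULL; ds <- NULL
    }
    grads[[l]] <- list(W = t(cc$A) %*% dZ, b = colSums(dZ), g = dg, s = ds)
    if (l > 1) dA <- dZ %*% t(ly$W)
  }
  grads
}

adam_init <- function(net) {
  lapply(net$layers, function(ly) {
    lapply(ly, function(p) list(m = p * 0, v = p * 0))
  })
}

adam_step <- function(net, grads, state, lr, t_step,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in seq_along(net$layers)) {
    for (nm in names(net$layers[[l]])) {
      g <- grads[[l]][[nm]]
      if (is.null(g)) next
      st <- state[[l]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^t_step)
      vhat <- st$v / (1 - beta2^t_step)
      net$layers[[l]][[nm]] <- net$layers[[l]][[nm]] -
        lr * mhat / (sqrt(vhat) + eps)
      state[[l]][[nm]] <- st
    }
  }
  list(net = net, state = state)
}

#' Assemble growth-network features for one trajectory
#'
#' Feature layout (2k+3): k specific rates, k concentrations, previous-step
#' biomaterial, time, and time step. The previous predicted growth rate
#' enters through the biomaterial recurrence rather than as a separate
#' input.
#'
#' @param rates n_times x k matrix of specific rates.
#' @param concs n_times x k matrix of concentrations.
#' @param times time points (d), strictly increasing.
#' @param gamma biomaterial value per time point (1e6 cells.d/ml).
#' @return n_times x (2k+3) feature matrix.
#' @export
growth_features <- function(rates, concs, times, gamma) {
  if (is.unsorted(times, strictly = TRUE)) {
    stop("features must be ordered strictly in time")
  }
  nt <- length(times)
  dt <- c(diff(times)[1], diff(times))
  stopifnot(nrow(rates) == nt, nrow(concs) == nt, length(gamma) == nt)
  cbind(rates, concs, gamma, times, dt)
}

#' Predict a growth-rate trajectory
#'
#' Runs the baseline + deviation predictor along a time-ordered feature
#' sequence, self-feeding the biomaterial recurrence: at each step the
#' previous predicted growth rate updates the viable-cell estimate, which
#' accrues into the biomaterial input of the next step.
#'
#' @param model a `growth_model` from [train_growth_nn()] (or a list with
#'   `baseline`, `net`, `scaler`).
#' @param rates,concs n_times x k matrices.
#' @param times time points (d).
#' @param Xv0 initial viable cell density (1e6 cells/ml).
#' @param gamma0 initial biomaterial.
#' @return data.frame(time_d, mu, Xv, gamma).
#' @export
predict_mu <- function(model, rates, concs, times, Xv0, gamma0 = 0) {
  if (is.unsorted(times, strictly = TRUE)) {
    stop("features must be ordered strictly in time")
  }
  nt <- length(times)
  k <- ncol(rates)
  mu <- numeric(nt)
  Xv <- numeric(nt)
  gamma <- numeric(nt)
  Xv_cur <- Xv0; gamma_cur <- gamma0
  mu_prev <- model$baseline$fun(times[1])
  dts <- c(diff(times)[1], diff(times))
  for (i in seq_len(nt)) {
    x <- c(rates[i, ], concs[i, ], gamma_cur, times[i], dts[i])
    xs <- scale_apply(model$scaler, matrix(x, 1))
    dev <- mlp_forward(model$net, xs, training = FALSE)$y
    mu[i] <- model$baseline$fun(times[i]) + dev
    Xv[i] <- Xv_cur; gamma[i] <- gamma_cur
    if (i < nt) {
      up <- recurrence_step(Xv_cur, mu[i], gamma_cur, diff(times)[i])
      Xv_cur <- up[["Xv"]]; gamma_cur <- up[["gamma"]]
    }
  }
  data.frame(time_d = times, mu = mu, Xv = Xv, gamma = gamma)
}

scale_fit <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd < 1e-12] <- 1
  list(mean = mu, sd = sd)
}
scale_apply <- function(sc, X) {
  sweep(sweep(X, 2, sc$mean), 2, sc$sd, "/")
}

#' Train the growth-rate predictor
#'
#' Batch-wise sequential training: each epoch presents the batches in
#' random order; per batch the deviation network predicts all trajectories,
#' the composite loss ([compute_loss()]) is evaluated and one
#' backpropagation/optimiser step taken. During training the biomaterial
#' input is teacher-forced from the target growth trajectories; at
#' inference ([predict_mu()]) it is self-fed.
#'
#' @param batches list; each element describes one culture with `times`
#'   (n_times), `mu` (n_traj x n_times target growth-rate draws), `rates`
#'   (n_times x k or n_traj x n_times x k), `concs` (n_times x k), `Xv0`.
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param dropout dropout rate.
#' @param max_time_points trajectories are truncated to this many points.
#' @param seed seed controlling init, shuffling and dropout.
#' @param baseline optional pre-fitted [fit_baseline()] model.
#' @return object of class `growth_model`: `baseline`, `net`, `scaler`,
#'   `loss_history` (per epoch), `k`.
#' @export
train_growth_nn <- function(batches, epochs = 250, lr = 1e-3,
                            dropout = 0.1, max_time_points = 32,
                            seed = 1, baseline = NULL) {
  stopifnot(length(batches) >= 1)
  if (is.null(baseline)) {
    pooled <- do.call(rbind, lapply(batches, function(b) {
      data.frame(time_d = b$times, mu = colMeans(b$mu))
    }))
    baseline <- fit_baseline(pooled, seed = seed)
  }
  k <- ncol(batches[[1]]$concs)
  prep <- lapply(batches, function(b) {
    nt <- min(length(b$times), max_time_points)
    idx <- seq_len(nt)
    times <- b$times[idx]
    dts <- c(diff(times)[1], diff(times))
    n_traj <- nrow(b$mu)
    # teacher-forced biomaterial per trajectory from target mu draws
    feats <- vector("list", n_traj)
    for (n in seq_len(n_traj)) {
      Xv <- b$Xv0; gam <- 0
      gtraj <- numeric(nt)
      for (i in seq_len(nt)) {
        gtraj[i] <- gam
        if (i < nt) {
          up <- recurrence_step(Xv, b$mu[n, i], gam, diff(times)[i])
          Xv <- up[["Xv"]]; gam <- up[["gamma"]]
        }
      }
      rmat <- if (length(dim(b$rates)) == 3) {
        matrix(b$rates[n, idx, ], nt, k)
      } else b$rates[idx, , drop = FALSE]
      feats[[n]] <- cbind(rmat, b$concs[idx, , drop = FALSE], gtraj,
                          times, dts)
    }
    X <- do.call(rbind, feats)           # (n_traj*nt) x (2k+3)
    list(X = X, mu = b$mu[, idx, drop = FALSE], times = times,
         n_traj = n_traj, nt = nt,
         w_traj = trajectory_weights(b$mu[, idx, drop = FALSE]),
         w_time = time_weights(times, max(times)),
         base = baseline$fun(times))
  })
  scaler <- scale_fit(do.call(rbind, lapply(prep, `[[`, "X")))
  net <- init_deviation_network(2 * k + 3, dropout = dropout, seed = seed)
  state <- adam_init(net)
  loss_hist <- numeric(epochs)
  t_step <- 0
  with_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample(length(prep))
      ep_loss <- 0
      for (bi in ord) {
        p <- prep[[bi]]
        Xs <- scale_apply(scaler, p$X)
        fw <- mlp_forward(net, Xs, training = lr > 0)
        pred <- matrix(fw$y, p$n_traj, p$nt, byrow = TRUE) +
          matrix(p$base, p$n_traj, p$nt, byrow = TRUE)
        lc <- compute_loss(pred, p$mu, p$w_traj, p$w_time)
        if (!is.finite(lc$total)) {
          stop(sprintf("divergent training loss at epoch %d", ep))
        }
        ep_loss <- ep_loss + lc$total
        if (lr > 0) {
          dpred <- loss_grad(pred, p$mu, p$w_traj, p$w_time)
          dy <- as.vector(t(dpred))
          grads <- mlp_backward(net, fw$cache, dy)
          t_step <- t_step + 1
          up <- adam_step(net, grads, state, lr, t_step)
          net <- up$net; state <- up$state
        }
      }
      loss_hist[ep] <- ep_loss / length(prep)
    }
  })
  structure(list(baseline = baseline, net = net, scaler = scaler,
                 loss_history = loss_hist, k = k),
            class = "growth_model")
}

# analytic gradient of compute_loss wrt predictions
loss_grad <- function(pred, targ, w_traj, w_time) {
  n <- nrow(pred); nt <- ncol(pred)
  g <- 2 * (pred - targ) * outer(w_traj, w_time) / nt
  S <- sum(colMeans(pred) - colMeans(targ))
  g <- g + sign(S) / n
  if (nt >= 3) {
    d2 <- pred[, -c(1, 2), drop = FALSE] -
      2 * pred[, -c(1, nt), drop = FALSE] +
      pred[, -c(nt - 1, nt), drop = FALSE]
    s <- sign(d2) / n
    g[, -c(1, 2)] <- g[, -c(1, 2)] + s
    g[, -c(1, nt)] <- g[, -c(1, nt)] - 2 * s
    g[, -c(nt - 1, nt)] <- g[, -c(nt - 1, nt)] + s
  }
  g
}
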