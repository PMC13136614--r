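test_that("feature assembly yields 2k + 3 features and excludes the right metabolites", {
  an <- chotwin_analytes()
  expect_length(an$growth_nn, 21)
  expect_identical(setdiff(an$all, an$growth_nn),
                   c("VCD", "Glc", "Lac", "NH4"))
  k <- 21; nt <- 5
  X <- growth_features(matrix(0, nt, k), matrix(0, nt, k), 1:5,
                       rep(0, nt))
  expect_equal(ncol(X), 2 * k + 3)
  expect_error(growth_features(matrix(0, 3, k), matrix(0, 3, k),
                               c(1, 3, 2), rep(0, 3)),
               "ordered strictly in time")
})

test_that("baseline refits recover a 4-sigmoid growth profile", {
  par_true <- c(0.62, 6, -1, 0.10, 2.5, -0.6, -0.11, 9.5, 0.8,
                -0.02, 12.5, 0.5, 0)
  tt <- seq(0, 14, 0.25)
  fit <- fit_baseline(data.frame(time_d = tt,
                                 mu = sigmoid_sum(par_true, tt)),
                      seed = 4)
  expect_lt(fit$rmse, 1e-6)
  expect_lt(max(abs(fit$fun(tt) - sigmoid_sum(par_true, tt))), 1e-5)
})

test_that("baseline reproduces a constant growth rate", {
  tt <- 0:14
  fit <- fit_baseline(data.frame(time_d = tt, mu = rep(0.03, 15)),
                      seed = 1)
  expect_lt(max(abs(fit$fun(tt) - 0.03)), 1e-3)
})

test_that("a single-batch baseline proceeds with a warning", {
  e <- rate_ensemble(0:5, matrix(0.03, 3, 6), analyte = "mu")
  expect_warning(fit_baseline(list(e), seed = 1), "single batch")
})

test_that("trajectory weights favour representative trajectories", {
  w_same <- trajectory_weights(matrix(0.05, 4, 3))
  expect_equal(w_same, rep(0.25, 4))
  w <- trajectory_weights(matrix(c(0.02, 0.03, 0.10), 3, 1))
  expect_true(w[2] > w[1] && w[1] > w[3])
  expect_equal(sum(w), 1)
  m <- matrix(c(0.05, 0.05, 0.05, 0.5), 4, 1)
  expect_identical(which.min(trajectory_weights(m)), 4L)
})

test_that("time weights decrease linearly to zero", {
  expect_equal(time_weights(0, 10), 1)
  expect_equal(time_weights(10, 10), 0)
  expect_equal(time_weights(5, 10), 0.5)
})

test_that("loss components match hand-computed cases", {
  targ <- matrix(rnorm(12), 3, 4)
  lc <- compute_loss(targ, targ)
  expect_equal(lc$weighted_mse, 0)
  expect_equal(lc$mean_matching, 0)
  expect_equal(lc$total, lc$weighted_mse + lc$mean_matching +
                 lc$smoothness)
  # affine-in-time predictions carry no curvature penalty
  lin <- matrix(seq(0, 2, length.out = 5), 1)
  expect_equal(compute_loss(lin, lin * 0)$smoothness, 0)
  # 3-point hand example: second difference -2, contribution 2
  expect_equal(compute_loss(matrix(c(0, 1, 0), 1), matrix(0, 1, 3),
                            dt = 1)$smoothness, 2)
  expect_error(compute_loss(matrix(NaN, 1, 3), matrix(0, 1, 3)),
               "non-finite")
})

test_that("loss gradients agree with numerical differentiation", {
  set.seed(42)
  k <- 3; nf <- 2 * k + 3
  net <- init_deviation_network(nf, widths = c(8, 6, 1), dropout = 0,
                                seed = 2)
  n_traj <- 4; nt <- 5
  X <- matrix(rnorm(n_traj * nt * nf), n_traj * nt, nf)
  targ <- matrix(rnorm(n_traj * nt), n_traj, nt)
  wtr <- trajectory_weights(targ)
  wti <- time_weights(1:nt, nt)
  lossf <- function(net) {
    y <- chotwin:::mlp_forward(net, X)$y
    compute_loss(matrix(y, n_traj, nt, byrow = TRUE), targ, wtr,
                 wti)$total
  }
  fw <- chotwin:::mlp_forward(net, X)
  dpred <- chotwin:::loss_grad(matrix(fw$y, n_traj, nt, byrow = TRUE),
                               targ, wtr, wti)
  grads <- chotwin:::mlp_backward(net, fw$cache, as.vector(t(dpred)))
  for (l in 1:3) {
    for (nm in c("W", "b", "g", "s")) {
      if (is.null(grads[[l]][[nm]])) next
      P <- net$layers[[l]][[nm]]
      for (j in seq_len(min(3, length(P)))) {
        eps <- 1e-6
        n2 <- net
        n2$layers[[l]][[nm]][j] <- P[j] + eps
        f1 <- lossf(n2)
        n2$layers[[l]][[nm]][j] <- P[j] - eps
        f0 <- lossf(n2)
        num <- (f1 - f0) / (2 * eps)
        expect_lt(abs(num - grads[[l]][[nm]][j]) / (abs(num) + 1e-8),
                  1e-5)
      }
    }
  }
})

test_that("the recurrence matches the discrete update by hand", {
  s1 <- recurrence_step(1, 0.1, 0, 1)
  s2 <- recurrence_step(s1[["Xv"]], 0.1, s1[["gamma"]], 1)
  expect_equal(s2[["Xv"]], 1.21)
  expect_equal(s2[["gamma"]], 2.1)
  # mu = 0: Xv constant, gamma accrues linearly
  s <- recurrence_step(2, 0, 5, 0.5)
  expect_equal(s[["Xv"]], 2)
  expect_equal(s[["gamma"]], 6)
  s0 <- recurrence_step(0, 0.3, 0, 1)
  expect_equal(s0[["gamma"]], 0)
})

test_that("VCD integration of a constant baseline is exponential", {
  mu <- 0.2; dt <- 0.01
  Xv <- 1; gam <- 0
  for (i in 1:500) {
    up <- recurrence_step(Xv, mu, gam, dt)
    Xv <- up[["Xv"]]; gam <- up[["gamma"]]
  }
  expect_equal(Xv, exp(mu * 5), tolerance = 1e-2)
})

mini_batches <- function(n_batches = 3, n_traj = 8, seed = 9) {
  set.seed(seed)
  k <- 4; nt <- 8
  lapply(seq_len(n_batches), function(b) {
    mu_true <- 0.5 * plogis(-(1:nt - 4)) + 0.05 * b / 10
    mu <- matrix(rep(mu_true, each = n_traj), n_traj) +
      matrix(rnorm(n_traj * nt, 0, 0.02), n_traj)
    list(times = 1:nt, mu = mu,
         rates = matrix(rnorm(nt * k, -0.01, 0.004), nt, k),
         concs = matrix(runif(nt * k, 0.1, 2), nt, k), Xv0 = 0.3)
  })
}

test_that("training is deterministic and reduces the loss", {
  b <- mini_batches()
  m1 <- train_growth_nn(b, epochs = 25, seed = 5)
  m2 <- train_growth_nn(b, epochs = 25, seed = 5)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_lt(tail(m1$loss_history, 1), 0.5 * m1$loss_history[1])
})

test_that("a zero learning rate leaves parameters untouched", {
  b <- mini_batches()
  m0 <- train_growth_nn(b, epochs = 1, lr = 0, seed = 5)
  ref <- init_deviation_network(2 * 4 + 3, dropout = 0.1, seed = 5)
  expect_identical(m0$net$layers, ref$layers)
  expect_length(m0$loss_history, 1)
})

test_that("a zeroed deviation head reproduces the baseline exactly", {
  b <- mini_batches()
  m <- train_growth_nn(b, epochs = 5, seed = 5)
  L <- length(m$net$layers)
  m$net$layers[[L]]$W[] <- 0
  m$net$layers[[L]]$b[] <- 0
  pr <- predict_mu(m, b[[1]]$rates, b[[1]]$concs, b[[1]]$times, 0.3)
  expect_equal(pr$mu, m$baseline$fun(b[[1]]$times))
  expect_error(predict_mu(m, b[[1]]$rates, b[[1]]$concs,
                          rev(b[[1]]$times), 0.3),
               "ordered strictly in time")
})

test_that("the trained deviation network beats the baseline on held-out data", {
  tw <- fx_twin_setup()
  gm <- tw$growth_model
  # an unseen batch from an off-centre media group: the pooled baseline is
  # biased there, the feature-driven deviation is not
  test <- generate_batch(synthetic_config(n_batches = 6,
                                          n_media_groups = 3,
                                          noise_cv = 0.05, seed = 1),
                         1, seed = 999)
  rt <- truth_rates(test, times = 0:14)
  an <- chotwin_analytes()$growth_nn
  rmat <- sapply(an, function(a) rt$rate[rt$analyte == a])
  pre <- test$truth$latent[test$truth$latent$phase == 0, ]
  concs <- as.matrix(pre[match(0:14, pre$time_d), an])
  mu_true <- rt$rate[rt$analyte == "VCD"]
  pr <- predict_mu(gm, rmat, concs, 0:14, 0.3)
  rmse_nn <- sqrt(mean((pr$mu - mu_true)^2))
  rmse_base <- sqrt(mean((gm$baseline$fun(0:14) - mu_true)^2))
  expect_lt(rmse_nn, rmse_base)
})
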