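test_that("raw to pseudo to raw round trip is lossless", {
  b <- fx_batch_noisy()
  for (a in c("Glc", "Gln", "Ala", "titer")) {
    ps <- volume_correct(b$record, a)
    raw <- apply_event_steps(ps$values, ps$events, ps$times)
    expect_equal(raw, ps$raw, tolerance = 1e-10, info = a)
  }
})

test_that("volume correction is the identity before any feed", {
  b <- fx_batch_noisy()
  ps <- volume_correct(b$record, "Glc")
  early <- ps$times < 3
  expect_identical(ps$values[early], ps$raw[early])
})

test_that("a bolus at the current concentration leaves both series flat", {
  rec <- process_record(
    batch_id = "b", media_group = 1,
    samples = data.frame(time_d = 0:4, analyte = "Glc", value = 5),
    feeds = data.frame(time_d = 2, stream = "FMA", volume_ml = 5),
    compositions = data.frame(stream = "FMA", analyte = "Glc",
                              conc_g_per_l = 5),
    v0 = 10, sample_volume = 0)
  ps <- volume_correct(rec, "Glc")
  expect_equal(ps$values, rep(5, 5))
  expect_equal(ps$events$delta, 0)
})

test_that("a feed-free dilution-free record needs no correction", {
  rec <- process_record(
    batch_id = "b", media_group = 1,
    samples = data.frame(time_d = 0:5, analyte = "Glc",
                         value = c(6, 5, 4.2, 3.1, 2.5, 2)),
    feeds = data.frame(time_d = numeric(), stream = character(),
                       volume_ml = numeric()),
    compositions = data.frame(stream = "FMA", analyte = "Glc",
                              conc_g_per_l = 1),
    v0 = 10)
  ps <- volume_correct(rec, "Glc")
  expect_identical(ps$values, ps$raw)
})

test_that("a missing stream composition is reported by name", {
  rec <- process_record(
    batch_id = "b", media_group = 1,
    samples = data.frame(time_d = 0:4, analyte = "Glc", value = 5),
    feeds = data.frame(time_d = 2, stream = "FMX", volume_ml = 5),
    compositions = data.frame(stream = "FMA", analyte = "Glc",
                              conc_g_per_l = 5),
    v0 = 10, sample_volume = 0)
  expect_error(volume_correct(rec, "Glc"), "FMX")
})

test_that("model selection recovers the generating basis order", {
  tt <- seq(0, 14, 1)
  ser1 <- structure(list(times = tt, values = sigmoid_sum(c(5, 6, 1.5, 2),
                                                          tt),
                         events = NULL, analyte = "x", batch = "b"),
                    class = "pseudo_series")
  fit1 <- fit_basis(ser1, max_basis = 3, seed = 2)
  expect_identical(fit1$n_basis, 1L)
  pm <- colMeans(basis_curves(fit1, tt))
  expect_lt(max(abs(pm - ser1$values)) / max(abs(ser1$values)), 0.01)

  t2 <- seq(0, 14, length.out = 30)
  set.seed(7)
  v2 <- sigmoid_sum(c(5, 4, 1, -3, 10, 0.8, 2), t2) + rnorm(30, 0, 0.02)
  ser2 <- structure(list(times = t2, values = v2, events = NULL,
                         analyte = "y", batch = "b"),
                    class = "pseudo_series")
  fit2 <- fit_basis(ser2, max_basis = 3, seed = 3)
  expect_gt(fit2$log_evidence[2], fit2$log_evidence[1] + 1)
})

test_that("a constant series yields a flat fit with near-zero derivative", {
  tt <- 0:14
  ser <- structure(list(times = tt, values = rep(2, 15), events = NULL,
                        analyte = "z", batch = "b"),
                   class = "pseudo_series")
  fit <- fit_basis(ser, max_basis = 2, seed = 4)
  expect_lt(max(abs(colMeans(basis_curves(fit, tt)) - 2)), 1e-3)
  expect_lt(max(abs(colMeans(basis_curves(fit, tt, derivative = TRUE)))),
            1e-3)
})

test_that("too-short series are rejected", {
  ser <- structure(list(times = 0:2, values = c(1, 2, 3), events = NULL),
                   class = "pseudo_series")
  expect_error(fit_basis(ser), "at least 4")
})

test_that("sampled rates equal the analytic derivative over constant VCD", {
  tt <- 0:14
  par1 <- c(5, 6, 1.5, 2)
  ser <- structure(list(times = tt, values = sigmoid_sum(par1, tt),
                        events = NULL, analyte = "x", batch = "b"),
                   class = "pseudo_series")
  fit <- fit_basis(ser, max_basis = 1, seed = 2)
  # exact-derivative oracle: a degenerate posterior at the true parameters
  fit_exact <- fit
  fit_exact$draws <- matrix(rep(c(par1, 0), each = 3), 3)
  ens0 <- sample_rates(fit_exact, vcd = 2, times = tt, n_traj = 3,
                       seed = 3)
  expect_lt(max(abs(ens0$mean - sigmoid_sum_deriv(par1, tt) / 2)), 1e-6)
  expect_equal(ens0$p5, ens0$mean)   # degenerate ensemble collapses
  ens <- sample_rates(fit, vcd = 2, times = tt, n_traj = 100, seed = 3)
  truth <- sigmoid_sum_deriv(par1, tt) / 2
  expect_equal(dim(ens$trajectories), c(100L, 15L))
  expect_lt(max(abs(ens$mean - truth)), 5e-4)
  expect_true(all(ens$p5 <= ens$mean + 1e-12))
  expect_true(all(ens$mean <= ens$p95 + 1e-12))
  expect_error(sample_rates(fit, vcd = 2, times = c(0, 20)),
               "outside the fitted horizon")
  expect_error(sample_rates(fit, vcd = 0, times = tt), "VCD")
})

test_that("a degenerate single-draw ensemble collapses its band", {
  e <- rate_ensemble(0:3, matrix(rep(c(1, 2, 3, 4), 5), 5, byrow = TRUE))
  expect_equal(e$p5, e$mean)
  expect_equal(e$p95, e$mean)
})

test_that("ensemble mean rates are invariant to grid refinement", {
  tt <- 0:14
  ser <- structure(list(times = tt, values = sigmoid_sum(c(5, 6, 1.5, 2),
                                                         tt),
                        events = NULL, analyte = "x", batch = "b"),
                   class = "pseudo_series")
  fit <- fit_basis(ser, max_basis = 1, seed = 2)
  coarse <- sample_rates(fit, 1, times = seq(0, 14, 2), seed = 9)
  fine <- sample_rates(fit, 1, times = seq(0, 14, 0.25), seed = 9)
  interp <- approx(fine$times, fine$mean, xout = coarse$times)$y
  expect_equal(coarse$mean, interp, tolerance = 1e-6)
})

test_that("reconstruction reapplies events and honours the tie rule", {
  b <- fx_batch_clean()
  ps <- volume_correct(b$record, "Glc")
  fit <- fit_basis(ps, max_basis = 3, seed = 5)
  rec <- reconstruct_concentrations(fit, ps$times)
  med <- apply(rec, 2, median)
  # noise-free data: the median reconstruction tracks the raw measurements
  expect_lt(max(abs(med - ps$raw)) / max(ps$raw), 0.05)
  # no events before the feed start: reconstruction equals the curves
  early <- ps$times[ps$times < 3]
  expect_equal(reconstruct_concentrations(fit, early),
               basis_curves(fit, early))
  # at an event time the post-event value is returned
  ev_t <- ps$events$time[1]
  just_at <- reconstruct_concentrations(fit, ev_t)
  before <- reconstruct_concentrations(fit, ev_t - 1e-5)
  expect_equal(mean(just_at) - mean(before), ps$events$delta[1],
               tolerance = 1e-3)
})

test_that("growth-rate estimation recovers the latent profile", {
  b <- fx_batch_clean()
  g <- estimate_growth(b$record, seed = 3)
  mu_true <- sigmoid_sum(b$truth$mu_par, g$mu$times)
  # error bounded by the derivative resolution of daily sampling: about
  # 15% of the growth-rate scale (~0.7/d) at the sharpest transition;
  # horizon boundaries carry the usual additional inflation
  interior <- g$mu$times >= 1 & g$mu$times <= 13
  expect_lt(max(abs(g$mu$mean - mu_true)[interior]), 0.15)
  # and the profile is tracked tightly away from the transition
  expect_lt(median(abs(g$mu$mean - mu_true)[interior]), 0.05)
})

test_that("posterior rate bands cover the true rates at default noise", {
  # growth-linked analytes whose true rate is smooth at the sampling
  # frequency; concentration-driven FLEX rates saw-tooth within feed days
  # and are only recoverable as daily averages
  b <- fx_batch_noisy()
  ens <- estimate_rates(b$record, analytes = c("Ala", "Ser", "Thr"),
                        seed = 2)
  rt <- truth_rates(b)
  cov <- vapply(c("Ala", "Ser", "Thr"), function(a) {
    e <- ens[[a]]
    truth <- rt$rate[rt$analyte == a][match(e$times,
                                            rt$time_d[rt$analyte == a])]
    mean(truth >= e$p5 & truth <= e$p95)
  }, numeric(1))
  expect_gte(mean(cov), 0.8)
})
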