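#' Ground-truth specific rates of a generated batch
#'
#' Evaluates the noise-free specific exchange rates (production positive)
#' that the generator used for every analyte of the panel: the kinetic
#' rate laws for the FLEX metabolites, the rank-2 loading model for amino
#' acids and titer, and the net growth rate for VCD.
#'
#' @param batch a `list(record, truth)` pair from [generate_batch()].
#' @param times evaluation times (d); defaults to the sampling grid.
#' @return data.frame(batch, group, time_d, analyte, rate).
#' @export
truth_rates <- function(batch, times = NULL) {
  tr <- batch$truth
  lat <- tr$latent
  pre <- lat[lat$phase == 0, ]
  if (is.null(times)) times <- sort(unique(batch$record$samples$time_d))
  at <- function(col) stats::approx(pre$time_d, pre[[col]], times,
                                    rule = 2)$y
  mu_eff <- at("mu_eff")
  p <- tr$params
  vGlc <- rate_glc(at("Glc"), at("Lac"), mu_eff, p)
  vLac <- rate_lac(vGlc, at("Lac"), p)
  vGlu <- rate_glu(at("Glu"), mu_eff, p)
  vGln <- rate_gln(at("Gln"), p)
  vNH4 <- rate_nh4(vGlu, vGln, p)
  rates <- list(
    VCD = at("mu_net"),
    Glc = -vGlc, Lac = vLac, Gln = -vGln, Glu = -vGlu, NH4 = vNH4,
    titer = tr$loadings$titer[["const"]] +
      tr$loadings$titer[["growth"]] * mu_eff)
  for (a in names(tr$loadings$aa_const)) {
    rates[[a]] <- -(tr$loadings$aa_const[[a]] +
                      tr$loadings$aa_growth[[a]] * mu_eff)
  }
  do.call(rbind, lapply(names(rates), function(a) {
    data.frame(batch = batch$record$batch_id, group = tr$group,
               time_d = times, analyte = a, rate = rates[[a]])
  }))
}

#' Ground-truth rate ensembles with synthetic posterior spread
#'
#' Wraps the exact generator rates of a batch into [rate_ensemble()]
#' objects with a configurable multiplicative spread, mimicking the shape
#' of estimated posterior ensembles. Useful for testing consumers of rate
#' ensembles (band statistics, constraints, loading models) independently
#' of the estimation layer.
#'
#' @param batch a `list(record, truth)` pair.
#' @param times evaluation times (d).
#' @param n_traj trajectories per ensemble.
#' @param spread relative trajectory spread.
#' @param seed RNG seed.
#' @return named list of [rate_ensemble()]s (one per analyte).
#' @export
truth_rate_ensembles <- function(batch, times = NULL, n_traj = 100,
                                 spread = 0.05, seed = 1) {
  rt <- truth_rates(batch, times)
  with_seed(seed, {
    out <- lapply(split(rt, rt$analyte), function(d) {
      base <- matrix(rep(d$rate, each = n_traj), n_traj)
      fac <- matrix(1 + stats::rnorm(n_traj, 0, spread),
                    n_traj, ncol(base))
      rate_ensemble(d$time_d, base * fac, analyte = d$analyte[1],
                    batch = d$batch[1])
    })
    out[unique(rt$analyte)]
  })
}
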