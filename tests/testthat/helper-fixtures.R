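# Shared fixtures, built lazily and cached for the test session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, .fixture_env)) {
    assign(name, builder(), .fixture_env)
  }
  get(name, .fixture_env)
}

fx_batch_clean <- function() {
  fixture("batch_clean", function() {
    generate_batch(synthetic_config(noise_cv = 0, seed = 1), 1, seed = 101)
  })
}

fx_batch_noisy <- function() {
  fixture("batch_noisy", function() {
    generate_batch(synthetic_config(noise_cv = 0.05, seed = 1), 2,
                   seed = 55)
  })
}

# constraint sets under which every reaction of the base toy network is
# active in at least one condition (growth phase / lactate-consumption
# phase)
toy_conditions <- function() {
  list(
    list(EX_glc = c(-10, -8), EX_gln = c(-5, -4), EX_lac = c(0.5, 2),
         EX_ala = c(0.1, 1), EX_mab = c(0.05, 1), EX_glu = c(-1, -0.1),
         EX_ser = c(-5, -0.1), EX_asp = c(-5, -0.1), EX_nh4 = c(0.05, 10)),
    list(EX_glc = c(-2, -1), EX_lac = c(-2, -0.5), EX_mab = c(0.01, 1),
         EX_ala = c(0.01, 1), EX_glu = c(-1, -0.01), EX_gln = c(-3, -0.5),
         EX_ser = c(-5, -0.05), EX_asp = c(-5, -0.05),
         EX_nh4 = c(0.01, 10)))
}

# an exchange-flux vector consistent with the toy stoichiometry
# (biomass 5, worked out by hand from the reaction list)
toy_consistent_exchanges <- function() {
  c(Glc = -2.5, Gln = -2.005, Glu = 0.5, Lac = 1, NH4 = 1, Ala = 0.5,
    Ser = -0.105, Asp = -0.105, titer = 0.1)
}

toy_exchange_of <- function() {
  c(Glc = "EX_glc", Gln = "EX_gln", Glu = "EX_glu", Lac = "EX_lac",
    NH4 = "EX_nh4", Ala = "EX_ala", Ser = "EX_ser", Asp = "EX_asp",
    titer = "EX_mab")
}

# full demo pipeline used by the twin integration tests and acceptance
# property suite: small cohort, loading model, band statistics, growth
# model, extended toy network
fx_twin_setup <- function() {
  fixture("twin_setup", function() {
    cfg <- synthetic_config(n_batches = 6, n_media_groups = 3,
                            noise_cv = 0.05, seed = 1)
    cohort <- generate_cohort(cfg)
    test_i <- 2
    train <- cohort[-test_i]
    tt <- seq(0, 14, 0.25)
    rates <- do.call(rbind, lapply(train, truth_rates, times = tt))
    tg <- window_pca(rates, window = 0.5, var_threshold = 0.90)
    lm_all <- train_loading_model(tg, feature_set = "ALL", seed = 3,
                                  maxit = 150)
    ens_list <- lapply(train, truth_rate_ensembles, times = 0:14,
                       n_traj = 30, seed = 5)
    analytes <- names(ens_list[[1]])
    pooled <- lapply(stats::setNames(nm = analytes), function(a) {
      rate_ensemble(0:14, do.call(rbind, lapply(ens_list, function(e) {
        e[[a]]$trajectories
      })), analyte = a)
    })
    band_fun <- band_statistics(pooled)
    gb <- lapply(train, function(b) {
      rt <- truth_rates(b, times = 0:14)
      an <- chotwin_analytes()$growth_nn
      rmat <- sapply(an, function(a) rt$rate[rt$analyte == a])
      pre <- b$truth$latent[b$truth$latent$phase == 0, ]
      sel <- match(0:14, pre$time_d)
      concs <- as.matrix(pre[sel, an])
      mu_true <- rt$rate[rt$analyte == "VCD"]
      n_traj <- 20
      mu <- matrix(rep(mu_true, each = n_traj), n_traj) *
        (1 + matrix(stats::rnorm(n_traj * 15, 0, 0.03), n_traj))
      list(times = 0:14, mu = mu, rates = rmat, concs = concs, Xv0 = 0.3)
    })
    set.seed(2)
    gm <- train_growth_nn(gb, epochs = 60, seed = 7)
    net <- generate_toy_network(extended_exchanges = TRUE)
    list(cohort = cohort, test = cohort[[test_i]], targets = tg,
         loading_model = lm_all, band_fun = band_fun, growth_model = gm,
         net = net,
         artifacts = list(growth_model = gm, params = kinetic_parameters(),
                          loading_model = lm_all, net = net,
                          band_fun = band_fun))
  })
}

twin_init_from <- function(batch) {
  s0 <- batch$record$samples[batch$record$samples$time_d == 0, ]
  init <- as.list(stats::setNames(s0$value, s0$analyte))
  init$Xd <- 0.002; init$Xl <- 0.001; init$gammaX <- 0; init$V <- 10
  init
}

fx_twin_run <- function() {
  fixture("twin_run", function() {
    tw <- fx_twin_setup()
    run_twin(twin_init_from(tw$test), tw$test$record$feeds,
             tw$test$record$compositions, tw$artifacts, horizon = 14,
             dt = 0.1)
  })
}
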