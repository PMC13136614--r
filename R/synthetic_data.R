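#' Configuration of the synthetic fed-batch study
#'
#' Defaults emulate the study design the package targets: 23 fed-batch
#' bioreactor runs over 8 media-formulation groups, daily sampling for 14
#' days, inoculation at 0.3e6 cells/ml, combined nutrient feeds (FMA + FMB)
#' added daily from day 3, and glucose stock (FMG, 400 g/l) additions
#' keeping glucose above 5 g/l from day 5 on.
#'
#' @param n_batches number of batches in the cohort.
#' @param n_media_groups number of distinct FMA+FMB formulations.
#' @param horizon culture duration (days).
#' @param sampling_interval sampling spacing (days).
#' @param inoculation_vcd starting viable cell density (1e6 cells/ml).
#' @param feed_start_day first FMA/FMB feeding day.
#' @param glucose_floor glucose maintenance threshold (g/l).
#' @param glucose_feed_start_day first FMG day.
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   measurement noise.
#' @param seed integer master seed; all group/batch draws derive from it.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_batches = 23, n_media_groups = 8,
                             horizon = 14, sampling_interval = 1,
                             inoculation_vcd = 0.3, feed_start_day = 3,
                             glucose_floor = 5, glucose_feed_start_day = 5,
                             noise_cv = 0.05, seed = 1) {
  cfg <- as.list(environment())
  stopifnot(n_media_groups <= n_batches, horizon > feed_start_day,
            noise_cv >= 0, sampling_interval > 0)
  structure(cfg, class = "synthetic_config")
}

# Ground-truth net growth profile: a 4-sigmoid sum (1/d), scaled per media
# group. Exponential growth to ~day 6, stationary transition, late decline.
mu_truth_par <- function(group_scale = 1) {
  c(0.62 * group_scale, 6.0, -1.0,
    0.10 * group_scale, 2.5, -0.6,
    -0.11, 9.5, 0.8,
    -0.02, 12.5, 0.5,
    0)
}

# Deterministic per-group blueprint: growth scale, feed compositions,
# rank-2 loading vectors for the non-FLEX analytes.
group_blueprint <- function(config, group_index) {
  stopifnot(group_index >= 1, group_index <= config$n_media_groups)
  an <- chotwin_analytes()
  aa_all <- setdiff(an$free_exchange, "titer")
  # cohort-level base loading directions, shared across media groups so
  # that leave-one-group-out generalisation is possible by construction
  base <- with_seed(config$seed * 1000L, {
    list(l1 = stats::setNames(stats::runif(length(aa_all), 0.002, 0.010),
                              aa_all),
         l2 = stats::setNames(stats::runif(length(aa_all), 0.010, 0.050),
                              aa_all))
  })
  with_seed(config$seed * 1000L + group_index, {
    scale <- if (config$n_media_groups == 1) 1 else
      seq(0.92, 1.08, length.out = config$n_media_groups)[group_index]
    aa <- setdiff(an$free_exchange, "titer")   # 18 amino acids
    fma <- data.frame(
      stream = "FMA",
      analyte = c("Glc", "Gln", "Glu", aa),
      conc_g_per_l = c(60, 6 * stats::runif(1, 0.8, 1.2),
                       3 * stats::runif(1, 0.8, 1.2),
                       6 * stats::runif(length(aa), 0.7, 1.3)))
    fmb <- data.frame(
      stream = "FMB",
      analyte = aa,
      conc_g_per_l = 10 * stats::runif(length(aa), 0.7, 1.3))
    fmg <- data.frame(stream = "FMG", analyte = "Glc", conc_g_per_l = 400)
    # loading vectors (g/1e9 cells/d): shared base directions with a mild
    # group-specific modulation
    load1 <- base$l1[aa] * (1 + stats::rnorm(length(aa), 0, 0.10))
    load2 <- base$l2[aa] * (1 + stats::rnorm(length(aa), 0, 0.10))
    list(group = group_index, mu_scale = scale,
         mu_par = mu_truth_par(scale),
         compositions = rbind(fma, fmb, fmg),
         aa_load_const = load1, aa_load_growth = load2,
         titer_load = c(const = 0.008, growth = 0.020))
  })
}

#' Generate one synthetic fed-batch culture
#'
#' Simulates the latent fed-batch dynamics (population balance, FLEX
#' metabolite kinetics with the reference parameter set, and rank-2
#' correlated amino-acid/titer exchange) with bolus feed events, then
#' samples it on the daily grid with multiplicative lognormal measurement
#' noise. Samples follow the pre-feed convention: the recorded value at a
#' feeding day is the concentration before that day's additions.
#'
#' @param config a [synthetic_config()].
#' @param group_index media group (1-based).
#' @param seed batch-level seed controlling feed-volume scale, batch factor
#'   jitter and measurement noise.
#' @param params kinetic parameters of the latent dynamics.
#' @return list with elements `record` (a [process_record()]) and `truth`
#'   (ground truth: `params`, `mu_par`, `mu_fun`, latent state table
#'   `latent` with pre/post event phases, the batch loading realisation and
#'   feed compositions).
#' @export
generate_batch <- function(config, group_index, seed,
                           params = kinetic_parameters()) {
  bp <- group_blueprint(config, group_index)
  an <- chotwin_analytes()
  aa <- setdiff(an$free_exchange, "titer")
  draws <- with_seed(seed, {
    list(feed_scale = stats::runif(1, 0.7, 1.3),
         eps = stats::rnorm(2, 0, 0.15))
  })
  # batch-level rank-2 jitter keeps rates in span{load1, load2}
  l1 <- bp$aa_load_const * (1 + draws$eps[1])
  l2 <- bp$aa_load_growth * (1 + draws$eps[2])
  titer_l <- bp$titer_load * (1 + draws$eps)
  mu_fun <- function(t) sigmoid_sum(bp$mu_par, t)

  state <- c(Xv = config$inoculation_vcd, Xd = 0.002, Xl = 0.001,
             gammaX = 0,
             Glc = 18, Lac = 0.1, Gln = 4.0, Glu = 0.5, NH4 = 0.05,
             titer = 0,
             stats::setNames(0.45 + 0.25 * stats::dnorm(seq_along(aa), 9, 5) *
                               10, aa))
  v <- 10                                  # ml working volume
  sample_volume <- 0.15
  rhs <- function(t, y) {
    r <- death_lysis_rates(y, params)
    mu_eff <- effective_growth(mu_fun(t), r[["mu_d"]], r[["mu_l"]])
    pop <- population_rhs(y, params, mu_eff, 0)
    flex <- flex_rhs(y[c("Glc", "Lac", "Gln", "Glu", "NH4")], params,
                     mu_eff, y[["Xv"]])
    extras <- c(titer = unname(titer_l["const"] + titer_l["growth"] * mu_eff),
                -(l1 + l2 * mu_eff)) * y[["Xv"]]
    names(extras) <- c("titer", aa)
    # smooth depletion cut-off keeps the system non-stiff near zero
    dep <- y[aa] / (y[aa] + 1e-3)
    extras[aa] <- ifelse(extras[aa] < 0, extras[aa] * dep, extras[aa])
    c(pop, flex, extras)
  }
  times <- seq(0, config$horizon, by = config$sampling_interval)
  fine <- sort(unique(c(times, seq(0, config$horizon, by = 0.1))))
  comp_of <- function(stream) {
    cc <- stats::setNames(rep(0, length(state)), names(state))
    rows <- bp$compositions[bp$compositions$stream == stream, ]
    cc[rows$analyte] <- rows$conc_g_per_l
    cc
  }
  bolus <- function(y, v, vol, stream) {
    cc <- comp_of(stream)
    (y * v + cc * vol) / (v + vol)
  }
  feeds <- data.frame(time_d = numeric(), stream = character(),
                      volume_ml = numeric())
  latent <- list()
  meas <- list()
  noise_sd <- sqrt(log(1 + config$noise_cv^2))
  noise <- with_seed(seed + 1L, {
    matrix(stats::rnorm(length(times) * length(an$all), 0, noise_sd),
           length(times), length(an$all), dimnames = list(NULL, an$all))
  })
  record_latent <- function(t, y, phase) {
    r <- death_lysis_rates(y, params)
    mu <- mu_fun(t)
    latent[[length(latent) + 1L]] <<- c(
      time_d = t, phase = if (phase == "pre") 0 else 1, y, V = v,
      mu_net = mu,
      mu_eff = effective_growth(mu, r[["mu_d"]], r[["mu_l"]]))
  }
  for (k in seq_along(times)) {
    t_k <- times[k]
    if (k > 1) {
      seg <- fine[fine >= times[k - 1] & fine <= t_k]
      sim <- integrate_events(rhs, state, seg)
      for (i in seq_along(seg)[-c(1, length(seg))]) {
        yv <- sim[i, -1]
        r0 <- death_lysis_rates(yv, params)
        latent[[length(latent) + 1L]] <- c(
          time_d = seg[i], phase = 0, yv, V = v, mu_net = mu_fun(seg[i]),
          mu_eff = effective_growth(mu_fun(seg[i]), r0[["mu_d"]],
                                    r0[["mu_l"]]))
      }
      state <- sim[nrow(sim), -1]
    }
    record_latent(t_k, state, "pre")
    # measurement (pre-event), then sampling loss, then feeds
    vals <- state[an$all[an$all != "VCD"]]
    vals <- c(VCD = state[["Xv"]], vals)
    meas[[k]] <- data.frame(
      time_d = t_k,
      analyte = c(names(vals), "viability", "volume"),
      value = c(unname(vals) * exp(noise[k, names(vals)]),
                100 * state[["Xv"]] / (state[["Xv"]] + state[["Xd"]]),
                v))
    v <- v - sample_volume
    if (t_k >= config$feed_start_day && t_k < config$horizon) {
      for (stream in c("FMA", "FMB")) {
        vol <- draws$feed_scale * v * if (stream == "FMA") 0.035 else 0.015
        state <- bolus(state, v, vol, stream)
        v <- v + vol
        feeds <- rbind(feeds, data.frame(time_d = t_k, stream = stream,
                                         volume_ml = vol))
      }
      if (t_k >= config$glucose_feed_start_day &&
          state[["Glc"]] < config$glucose_floor) {
        r0 <- death_lysis_rates(state, params)
        mu_eff0 <- effective_growth(mu_fun(t_k), r0[["mu_d"]], r0[["mu_l"]])
        # anticipatory sizing: fixed-point on the post-feed concentration so
        # the bolus covers the coming interval's consumption at that level
        xv_ahead <- state[["Xv"]] *
          exp(max(mu_fun(t_k), 0) * config$sampling_interval)
        target <- 2 * config$glucose_floor
        for (it in 1:4) {
          est <- rate_glc(target, state[["Lac"]], mu_eff0, params) *
            xv_ahead * config$sampling_interval
          target <- min(config$glucose_floor + 1.25 * est, 350)
        }
        vol <- v * (target - state[["Glc"]]) / (400 - target)
        state <- bolus(state, v, vol, "FMG")
        v <- v + vol
        feeds <- rbind(feeds, data.frame(time_d = t_k, stream = "FMG",
                                         volume_ml = vol))
      }
      record_latent(t_k, state, "post")
    }
  }
  latent <- as.data.frame(do.call(rbind, latent))
  record <- process_record(
    batch_id = sprintf("G%d-S%d", group_index, seed),
    media_group = group_index,
    samples = do.call(rbind, meas),
    feeds = feeds, compositions = bp$compositions,
    v0 = 10, sample_volume = sample_volume)
  truth <- list(params = params, mu_par = bp$mu_par, mu_fun = mu_fun,
                latent = latent, group = group_index,
                loadings = list(aa_const = l1, aa_growth = l2,
                                titer = titer_l),
                feed_scale = draws$feed_scale,
                compositions = bp$compositions)
  list(record = record, truth = truth)
}

#' Generate a synthetic cohort
#'
#' Batches are partitioned over media groups as evenly as possible (group
#' sizes differ by at most one); batches within a group share feed
#' compositions and the growth profile but differ in feed volumes and
#' measurement noise.
#'
#' @param config a [synthetic_config()].
#' @param params kinetic parameters of the latent dynamics.
#' @return list of `list(record, truth)` pairs, one per batch.
#' @export
generate_cohort <- function(config, params = kinetic_parameters()) {
  groups <- rep(seq_len(config$n_media_groups),
                length.out = config$n_batches)
  lapply(seq_len(config$n_batches), function(b) {
    generate_batch(config, groups[b], seed = config$seed + 37L * b,
                   params = params)
  })
}

#' Ground-truth inputs for kinetic-model identification
#'
#' Packages the noise-free latent trajectories of a generated batch into the
#' structures expected by [identify_population()] and [identify_flex()]
#' (interpolated Xv and effective-growth functions, observed concentration
#' matrix at sampling times, and the FLEX feed-event jumps implied by the
#' feed log).
#'
#' @param batch a `list(record, truth)` pair from [generate_batch()].
#' @return list with `population` and `flex` entries.
#' @export
identification_inputs <- function(batch) {
  rec <- batch$record
  lat <- batch$truth$latent
  pre <- lat[lat$phase == 0, ]
  # keep feed-event discontinuities: post rows shifted by the same 1e-6 d
  # offset used for event application during re-simulation
  traj <- lat[order(lat$time_d, lat$phase), ]
  tt <- traj$time_d + 1e-6 * traj$phase
  times <- sort(unique(rec$samples$time_d))
  at <- function(col) approx_left(pre, col, times)
  mu_net_fun <- batch$truth$mu_fun
  Xv_fun <- stats::approxfun(tt, traj$Xv, rule = 2)
  mu_eff_fun <- stats::approxfun(tt, traj$mu_eff, rule = 2)
  flex_events <- flex_feed_events(rec)
  list(
    population = list(times_d = times, Xv = at("Xv"), Xd = at("Xd"),
                      mu_net_fun = mu_net_fun,
                      events = dilution_events(rec)),
    flex = list(times_d = times,
                conc = {
                  m <- sapply(c("Glc", "Lac", "Gln", "Glu", "NH4"), at)
                  rownames(m) <- NULL; m
                },
                mu_eff_fun = mu_eff_fun, Xv_fun = Xv_fun,
                feed_events = flex_events))
}

approx_left <- function(pre, col, times) {
  stats::approx(pre$time_d, pre[[col]], xout = times, rule = 2)$y
}

#' Pure dilution jumps implied by a record's feed log
#'
#' Bolus feeds dilute every density-type state (cells, biomaterial) by
#' `V/(V + volume)` per addition. Events fire 1e-6 d after the sampling
#' instant (pre-feed sample convention).
#'
#' @param record a [process_record()].
#' @return data.frame(time, fun) or NULL if there are no feeds.
#' @export
dilution_events <- function(record) {
  if (!nrow(record$feeds)) return(NULL)
  ev_times <- sort(unique(record$feeds$time_d))
  funs <- lapply(ev_times, function(t) {
    evs <- record$feeds[record$feeds$time_d == t, ]
    evs <- evs[order(evs$stream), ]
    v_pre <- record_volume(record, t, when = "pre") -
      record$sample_volume * (t %in% record$samples$time_d)
    force(v_pre)
    function(y) {
      v <- v_pre
      for (i in seq_len(nrow(evs))) {
        y <- y * v / (v + evs$volume_ml[i])
        v <- v + evs$volume_ml[i]
      }
      y
    }
  })
  data.frame(time = ev_times + 1e-6, fun = I(funs))
}

#' FLEX-state feed-event jumps implied by a record's feed log
#'
#' Converts the bolus feed log into `integrate_events()`-style jump
#' functions acting on the five FLEX concentrations (the convention used for
#' fitting: samples are pre-feed, so jumps apply after the sample).
#'
#' @param record a [process_record()].
#' @return data.frame(time, fun) or NULL if there are no feeds.
#' @export
flex_feed_events <- function(record) {
  if (!nrow(record$feeds)) return(NULL)
  ev_times <- sort(unique(record$feeds$time_d))
  mets <- c("Glc", "Lac", "Gln", "Glu", "NH4")
  funs <- lapply(ev_times, function(t) {
    evs <- record$feeds[record$feeds$time_d == t, ]
    evs <- evs[order(evs$stream), ]
    v_pre <- record_volume(record, t, when = "pre") -
      record$sample_volume * (t %in% record$samples$time_d)
    force(v_pre)
    function(y) {
      v <- v_pre
      for (i in seq_len(nrow(evs))) {
        cin <- vapply(mets, function(m)
          feed_concentration(record, evs$stream[i], m), numeric(1))
        y <- (y * v + cin * evs$volume_ml[i]) / (v + evs$volume_ml[i])
        v <- v + evs$volume_ml[i]
      }
      y
    }
  })
  # feeds fire just after the sampling instant so that integrator output at
  # a sampling time is the pre-feed (measured) concentration
  data.frame(time = ev_times + 1e-6, fun = I(funs))
}
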