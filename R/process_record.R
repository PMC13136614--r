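#' Analyte vocabulary of the fed-batch panel
#'
#' The measured panel contains 25 analytes: viable cell density (VCD),
#' product titer, glucose, lactate, ammonium, and 20 amino acids (glutamine
#' and glutamate are both amino acids and members of the FLEX analyzer
#' panel). Derived subsets:
#' * `flex` - the five analyzer metabolites (Glc, Lac, Gln, Glu, NH4);
#' * `growth_nn` - the 21 metabolites fed to the growth-rate network
#'   (everything except VCD, glucose, lactate and ammonium);
#' * `free_exchange` - the 19 analytes whose exchange fluxes PC-dFBA
#'   predicts dynamically (everything except VCD and the FLEX five).
#'
#' @return named list of character vectors: `all`, `flex`, `amino_acids`,
#'   `growth_nn`, `free_exchange`.
#' @export
chotwin_analytes <- function() {
  aa18 <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gly", "His", "Ile", "Leu",
            "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp", "Tyr", "Val")
  flex <- c("Glc", "Lac", "Gln", "Glu", "NH4")
  all <- c("VCD", "titer", flex, aa18)
  list(all = all,
       flex = flex,
       amino_acids = c("Gln", "Glu", aa18),
       growth_nn = setdiff(all, c("VCD", "Glc", "Lac", "NH4")),
       free_exchange = setdiff(all, c("VCD", flex)))
}

#' Construct a fed-batch process record
#'
#' One batch worth of observed data: sampled analyte concentrations
#' (pre-feed convention: samples are drawn before the day's feed additions),
#' VCD/viability/volume, the bolus feed event log, and the feed-stream
#' compositions.
#'
#' @param batch_id character id.
#' @param media_group integer media-formulation group label.
#' @param samples data.frame(time_d, analyte, value); analytes from
#'   [chotwin_analytes()] plus `"viability"` (percent) and `"volume"` (ml).
#' @param feeds data.frame(time_d, stream, volume_ml).
#' @param compositions data.frame(stream, analyte, conc_g_per_l).
#' @param v0 initial reactor volume (ml).
#' @param sample_volume volume removed per sampling event (ml).
#' @return object of class `process_record`.
#' @export
process_record <- function(batch_id, media_group, samples, feeds,
                           compositions, v0, sample_volume = 0) {
  stopifnot(all(c("time_d", "analyte", "value") %in% names(samples)),
            all(c("time_d", "stream", "volume_ml") %in% names(feeds)),
            all(c("stream", "analyte", "conc_g_per_l") %in%
                  names(compositions)),
            all(samples$time_d >= 0), all(feeds$volume_ml >= 0))
  vocab <- c(chotwin_analytes()$all, "viability", "volume")
  bad <- setdiff(unique(samples$analyte), vocab)
  if (length(bad)) stop(sprintf("unknown analyte(s): %s",
                                paste(bad, collapse = ", ")))
  structure(list(batch_id = batch_id, media_group = media_group,
                 samples = samples[order(samples$time_d, samples$analyte), ],
                 feeds = feeds[order(feeds$time_d, feeds$stream), ],
                 compositions = compositions, v0 = v0,
                 sample_volume = sample_volume),
            class = "process_record")
}

#' @export
print.process_record <- function(x, ...) {
  cat(sprintf("<process_record '%s' (group %s): %d sampling times, %d analytes, %d feed events>\n",
              x$batch_id, x$media_group, length(unique(x$samples$time_d)),
              length(unique(x$samples$analyte)), nrow(x$feeds)))
  invisible(x)
}

#' Extract one analyte series from a record
#'
#' @param record a [process_record()].
#' @param analyte analyte name.
#' @return data.frame(time_d, value) sorted by time.
#' @export
record_series <- function(record, analyte) {
  s <- record$samples[record$samples$analyte == analyte, c("time_d", "value")]
  if (!nrow(s)) stop(sprintf("analyte '%s' not present in batch '%s'",
                             analyte, record$batch_id))
  rownames(s) <- NULL
  s
}

#' Reactor volume immediately before each event/sampling time
#'
#' Reconstructs V(t) from the initial volume, the feed log and per-sampling
#' losses. Bolus additions at time t and the sampling loss at time t are
#' ordered: sample first, then feeds.
#'
#' @param record a [process_record()].
#' @param times_d query times (days).
#' @param when `"pre"` (before that time's events) or `"post"` (after).
#' @return numeric volumes (ml).
#' @export
record_volume <- function(record, times_d,
                          when = c("post", "pre")) {
  when <- match.arg(when)
  sample_times <- sort(unique(record$samples$time_d))
  vapply(times_d, function(t) {
    inc <- if (when == "post") function(x) x <= t else function(x) x < t
    record$v0 -
      sum(inc(sample_times)) * record$sample_volume +
      sum(record$feeds$volume_ml[inc(record$feeds$time_d)])
  }, numeric(1))
}

#' Feed concentration of an analyte in a stream
#' @param record a [process_record()].
#' @param stream stream name; @param analyte analyte name.
#' @return concentration (g/l); 0 if the stream does not carry the analyte.
#' @export
feed_concentration <- function(record, stream, analyte) {
  comp <- record$compositions
  hit <- comp$stream == stream & comp$analyte == analyte
  if (!any(hit)) 0 else sum(comp$conc_g_per_l[hit])
}
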