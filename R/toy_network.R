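#' Generate a toy CHO-like metabolic network
#'
#' A small, stoichiometrically consistent network with a biomass objective,
#' antibody secretion, overflow lactate metabolism and glutaminolysis, whose
#' exchange reactions map onto the synthetic analyte panel. Optional
#' pathologies (each inserted exactly once) exercise the reduction pipeline:
#'
#' * `"dead_end"` - a metabolite that is only produced, making its producer
#'   blocked;
#' * `"blocked"` - a reaction whose substrate has no source;
#' * `"redundant_transport"` - a redundant two-step glucose transport route
#'   that parsimonious FBA never uses;
#' * `"infeasible_cycle"` - a thermodynamically infeasible internal 2-cycle.
#'
#' @param pathologies character vector of pathology names (may be empty).
#' @param extended_exchanges if TRUE, add exchange/transport/degradation
#'   triplets so that every analyte of [chotwin_analytes()] (except VCD,
#'   whose counterpart is the biomass reaction) has a mapped exchange: a
#'   25-analyte network for PC-dFBA tests.
#' @return a [metabolic_network()] with `analyte_map` set.
#' @export
generate_toy_network <- function(pathologies = character(),
                                 extended_exchanges = FALSE) {
  known <- c("dead_end", "blocked", "redundant_transport",
             "infeasible_cycle")
  bad <- setdiff(pathologies, known)
  if (length(bad)) {
    stop(sprintf("unknown pathology name(s): %s; known: %s",
                 paste(bad, collapse = ", "), paste(known, collapse = ", ")))
  }
  rx <- list(
    EX_glc  = list(c(glc_e = -1), -10, 0),
    EX_gln  = list(c(gln_e = -1), -5, 0),
    EX_glu  = list(c(glu_e = -1), -2, 2),
    EX_lac  = list(c(lac_e = -1), -5, 1000),
    EX_nh4  = list(c(nh4_e = -1), 0, 1000),
    EX_ala  = list(c(ala_e = -1), 0, 1000),
    EX_ser  = list(c(ser_e = -1), -5, 0),
    EX_asp  = list(c(asp_e = -1), -5, 0),
    EX_mab  = list(c(mab_e = -1), 0, 1000),
    GLCt    = list(c(glc_e = -1, glc_c = 1), 0, 1000),
    GLNt    = list(c(gln_e = -1, gln_c = 1), 0, 1000),
    GLUt    = list(c(glu_e = -1, glu_c = 1), -1000, 1000),
    LACt    = list(c(lac_c = -1, lac_e = 1), -1000, 1000),
    NH4t    = list(c(nh4_c = -1, nh4_e = 1), 0, 1000),
    ALAt    = list(c(ala_c = -1, ala_e = 1), 0, 1000),
    SERt    = list(c(ser_e = -1, ser_c = 1), 0, 1000),
    ASPt    = list(c(asp_e = -1, asp_c = 1), 0, 1000),
    GLYC    = list(c(glc_c = -1, pyr_c = 2), 0, 1000),
    LDH     = list(c(pyr_c = -1, lac_c = 1), -1000, 1000),
    RESP    = list(c(pyr_c = -1), 0, 1000),
    GLS     = list(c(gln_c = -1, glu_c = 1, nh4_c = 1), 0, 1000),
    ALATA   = list(c(pyr_c = -1, glu_c = -1, ala_c = 1), 0, 1000),
    BIOMASS = list(c(glc_c = -0.3, gln_c = -0.2, asp_c = -0.02,
                     ser_c = -0.02), 0, 1000),
    MABS    = list(c(gln_c = -0.05, asp_c = -0.05, ser_c = -0.05,
                     mab_e = 1), 0, 1000)
  )
  if ("dead_end" %in% pathologies) {
    rx$DEADP <- list(c(pyr_c = -1, dead_c = 1), 0, 1000)
  }
  if ("blocked" %in% pathologies) {
    rx$BLKC <- list(c(orphan_c = -1, pyr_c = 1), 0, 1000)
  }
  if ("redundant_transport" %in% pathologies) {
    # mass-conserving two-step duplicate of GLCt; pFBA never uses it
    rx$GLCt2a <- list(c(glc_e = -1, glcx_c = 1), 0, 1000)
    rx$GLCt2b <- list(c(glcx_c = -1, glc_c = 1), 0, 1000)
  }
  if ("infeasible_cycle" %in% pathologies) {
    rx$CYC1 <- list(c(cyca_c = -1, cycb_c = 1), 0, 1000)
    rx$CYC2 <- list(c(cycb_c = -1, cyca_c = 1), 0, 1000)
  }
  amap <- c(EX_glc = "Glc", EX_gln = "Gln", EX_glu = "Glu", EX_lac = "Lac",
            EX_nh4 = "NH4", EX_ala = "Ala", EX_ser = "Ser", EX_asp = "Asp",
            EX_mab = "titer")
  if (extended_exchanges) {
    # catch-all interconversion routes give the LP enough slack to track
    # kinetic rate laws that no fixed stoichiometry reproduces exactly
    rx$EX_ala[[2]] <- -10
    rx$ALAt[[2]] <- -1000
    rx$ALAd <- list(c(ala_c = -1, pyr_c = 1), -1000, 1000)
    rx$NH4d <- list(c(nh4_c = -1, pyr_c = 0.2), -1000, 1000)
    rx$GLUd <- list(c(glu_c = -1, pyr_c = 1), -1000, 1000)
    extra <- setdiff(chotwin_analytes()$free_exchange, c(amap, "titer"))
    for (a in extra) {
      low <- tolower(a)
      me <- paste0(low, "_e"); mc <- paste0(low, "_c")
      rx[[paste0("EX_", low)]] <- list(stats::setNames(-1, me), -10, 10)
      st <- stats::setNames(c(-1, 1), c(me, mc))
      rx[[paste0(toupper(low), "t")]] <- list(st, -1000, 1000)
      sd <- stats::setNames(c(-1, 1), c(mc, "pyr_c"))
      rx[[paste0(toupper(low), "d")]] <- list(sd, -1000, 1000)
      amap[paste0("EX_", low)] <- a
    }
  }
  mets <- unique(unlist(lapply(rx, function(r) names(r[[1]]))))
  S <- matrix(0, length(mets), length(rx),
              dimnames = list(mets, names(rx)))
  for (j in names(rx)) S[names(rx[[j]][[1]]), j] <- rx[[j]][[1]]
  lb <- vapply(rx, function(r) r[[2]], numeric(1))
  ub <- vapply(rx, function(r) r[[3]], numeric(1))
  metabolic_network(id = paste0("toy", if (length(pathologies))
                                  paste0("_", paste(sort(pathologies),
                                                    collapse = "_")) else ""),
                    S = S, lb = lb, ub = ub, objective = "BIOMASS",
                    analyte_map = amap)
}
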