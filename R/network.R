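#' Construct a constraint-based metabolic network
#'
#' Container for a stoichiometric model: metabolite/reaction tables, the
#' stoichiometric matrix `S`, flux bounds, the exchange subset and the
#' biomass/objective reaction. This is the object consumed by the reduction
#' pipeline and by PC-dFBA.
#'
#' @param id model identifier.
#' @param S stoichiometric matrix (metabolites x reactions), dimnames set.
#' @param lb,ub named flux bounds (mM/gDCW/h by convention).
#' @param objective id of the objective (biomass) reaction.
#' @param compartments named character vector metabolite id -> compartment.
#' @param analyte_map named character vector: exchange reaction id -> analyte
#'   name, for exchanges that correspond to measured extracellular analytes.
#' @return an object of class `metabolic_network`.
#' @export
metabolic_network <- function(id, S, lb, ub, objective,
                              compartments = NULL, analyte_map = NULL) {
  stopifnot(is.matrix(S), !is.null(rownames(S)), !is.null(colnames(S)))
  rxns <- colnames(S)
  lb <- lb[rxns]; ub <- ub[rxns]
  stopifnot(all(lb <= ub), objective %in% rxns)
  if (is.null(compartments)) {
    compartments <- stats::setNames(
      ifelse(grepl("_e$", rownames(S)), "e", "c"), rownames(S))
  }
  net <- structure(list(
    id = id, S = S, lb = lb, ub = ub, objective = objective,
    compartments = compartments,
    analyte_map = analyte_map %||% character()
  ), class = "metabolic_network")
  net
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf("<metabolic_network '%s': %d metabolites, %d reactions (%d exchanges), objective '%s'>\n",
              x$id, nrow(x$S), ncol(x$S), length(exchange_reactions(x)),
              x$objective))
  invisible(x)
}

#' Exchange reactions of a network
#'
#' An exchange is a reaction touching exactly one metabolite, and that
#' metabolite is extracellular (compartment `"e"`).
#'
#' @param net a [metabolic_network()].
#' @return character vector of reaction ids.
#' @export
exchange_reactions <- function(net) {
  nz <- colSums(net$S != 0)
  cand <- colnames(net$S)[nz == 1]
  keep <- vapply(cand, function(r) {
    m <- rownames(net$S)[net$S[, r] != 0]
    identical(unname(net$compartments[m]), "e")
  }, logical(1))
  cand[keep]
}

#' Flux balance analysis
#'
#' Maximises (default) or minimises the flux through `objective` subject to
#' `S v = 0` and the network bounds.
#'
#' @param net a [metabolic_network()].
#' @param objective reaction id; defaults to the network objective.
#' @param maximize logical.
#' @return list with `objective` (optimal value), `fluxes` (named vector),
#'   `status`.
#' @export
fba <- function(net, objective = net$objective, maximize = TRUE) {
  n <- ncol(net$S)
  obj <- stats::setNames(rep(0, n), colnames(net$S))
  obj[objective] <- if (maximize) -1 else 1
  sol <- solve_lp(obj, Aeq = net$S, beq = rep(0, nrow(net$S)),
                  lb = net$lb, ub = net$ub)
  list(objective = if (sol$status == "optimal")
         sum(sol$x[match(objective, colnames(net$S))]) else NA_real_,
       fluxes = stats::setNames(sol$x, colnames(net$S)),
       status = sol$status)
}

#' Parsimonious FBA
#'
#' Fixes the biomass optimum (within `opt_tol` relative), then minimises the
#' total absolute flux. Used to detect removable reactions during network
#' reduction.
#'
#' @inheritParams fba
#' @param opt_tol relative tolerance on the fixed optimum.
#' @return list with `fluxes`, `objective` (biomass at the pFBA solution),
#'   `total_flux`, `status`.
#' @export
pfba <- function(net, objective = net$objective, opt_tol = 1e-9) {
  base <- fba(net, objective)
  if (base$status != "optimal") return(base)
  n <- ncol(net$S)
  # split v = p - q, p,q >= 0; minimise sum(p + q)
  S2 <- cbind(net$S, -net$S)
  obj <- rep(1, 2 * n)
  lb2 <- c(pmax(net$lb, 0), pmax(-net$ub, 0))
  ub2 <- c(pmax(net$ub, 0), pmax(-net$lb, 0))
  j <- match(objective, colnames(net$S))
  fix <- rep(0, 2 * n); fix[j] <- 1; fix[n + j] <- -1
  lo <- base$objective - abs(base$objective) * opt_tol - 1e-12
  sol <- solve_lp(obj, Aeq = rbind(S2, fix),
                  beq = c(rep(0, nrow(net$S)), base$objective),
                  lb = lb2, ub = ub2)
  if (sol$status != "optimal") {
    # fall back to a soft band on the optimum
    sol <- solve_lp(obj, Aeq = S2, beq = rep(0, nrow(net$S)),
                    Ale = matrix(-fix, 1), ble = -lo,
                    lb = lb2, ub = ub2)
  }
  v <- sol$x[seq_len(n)] - sol$x[n + seq_len(n)]
  list(fluxes = stats::setNames(v, colnames(net$S)),
       objective = v[j], total_flux = sum(abs(v)), status = sol$status)
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux, optionally at a fixed fraction of
#' the biomass optimum.
#'
#' @inheritParams fba
#' @param reactions reaction ids to scan (default all).
#' @param fraction_of_optimum fix biomass >= fraction * optimum; use 0 to
#'   scan the whole feasible space.
#' @return data.frame with `reaction`, `min`, `max`.
#' @export
fva <- function(net, reactions = colnames(net$S), fraction_of_optimum = 0) {
  extra_Ale <- NULL; extra_ble <- NULL
  if (fraction_of_optimum > 0) {
    base <- fba(net)
    if (base$status != "optimal") stop("FVA: base FBA infeasible")
    j <- match(net$objective, colnames(net$S))
    row <- rep(0, ncol(net$S)); row[j] <- -1
    extra_Ale <- matrix(row, 1)
    extra_ble <- -fraction_of_optimum * base$objective
  }
  res <- t(vapply(reactions, function(r) {
    j <- match(r, colnames(net$S))
    obj <- rep(0, ncol(net$S)); obj[j] <- 1
    lo <- solve_lp(obj, Aeq = net$S, beq = rep(0, nrow(net$S)),
                   Ale = extra_Ale, ble = extra_ble,
                   lb = net$lb, ub = net$ub)
    hi <- solve_lp(-obj, Aeq = net$S, beq = rep(0, nrow(net$S)),
                   Ale = extra_Ale, ble = extra_ble,
                   lb = net$lb, ub = net$ub)
    c(if (lo$status == "optimal") lo$x[j] else NA_real_,
      if (hi$status == "optimal") hi$x[j] else NA_real_)
  }, numeric(2)))
  data.frame(reaction = reactions, min = res[, 1], max = res[, 2],
             row.names = NULL)
}

#' Modify reaction bounds
#'
#' @param net a [metabolic_network()].
#' @param reaction reaction id.
#' @param lb,ub new bounds (either may be NULL to keep current).
#' @return the modified network.
#' @export
set_bounds <- function(net, reaction, lb = NULL, ub = NULL) {
  if (!reaction %in% colnames(net$S)) {
    stop(sprintf("unknown reaction '%s'", reaction))
  }
  if (!is.null(lb)) net$lb[reaction] <- lb
  if (!is.null(ub)) net$ub[reaction] <- ub
  net
}

#' Remove reactions (and orphaned metabolites) from a network
#'
#' @param net a [metabolic_network()].
#' @param reactions ids to drop.
#' @param drop_orphans drop metabolites no longer used by any reaction.
#' @return the reduced network.
#' @export
remove_reactions <- function(net, reactions, drop_orphans = TRUE) {
  keep <- setdiff(colnames(net$S), reactions)
  S <- net$S[, keep, drop = FALSE]
  if (drop_orphans) {
    used <- rowSums(S != 0) > 0
    S <- S[used, , drop = FALSE]
  }
  net$S <- S
  net$lb <- net$lb[keep]
  net$ub <- net$ub[keep]
  net$compartments <- net$compartments[rownames(S)]
  net$analyte_map <- net$analyte_map[intersect(names(net$analyte_map), keep)]
  net
}

#' Add a reaction to a network
#'
#' @param net a [metabolic_network()].
#' @param id new reaction id.
#' @param stoich named numeric vector metabolite -> coefficient; metabolites
#'   not yet in the network are added (compartment inferred from the id
#'   suffix).
#' @param lb,ub flux bounds.
#' @return the extended network.
#' @export
add_reaction <- function(net, id, stoich, lb = -1000, ub = 1000) {
  if (id %in% colnames(net$S)) stop(sprintf("reaction '%s' exists", id))
  new_mets <- setdiff(names(stoich), rownames(net$S))
  if (length(new_mets)) {
    net$S <- rbind(net$S, matrix(0, length(new_mets), ncol(net$S),
                                 dimnames = list(new_mets, colnames(net$S))))
    net$compartments[new_mets] <- ifelse(grepl("_e$", new_mets), "e", "c")
  }
  col <- stats::setNames(rep(0, nrow(net$S)), rownames(net$S))
  col[names(stoich)] <- stoich
  net$S <- cbind(net$S, matrix(col, ncol = 1, dimnames = list(NULL, id)))
  net$lb[id] <- lb
  net$ub[id] <- ub
  net
}
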