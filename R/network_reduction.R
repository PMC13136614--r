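#' Map rate ensembles onto exchange-flux constraints
#'
#' Converts the 5th/95th percentile band of measured specific-rate
#' ensembles into bounds on the corresponding exchange reactions
#' (production positive, matching the exchange convention). The
#' cell-specific rates (g/1e9 cells/d) are scaled by a configurable
#' conversion factor into the network's flux unit (mM/gDCW/h); the factor
#' collapses cell mass and molar mass and defaults to 1 (toy networks).
#'
#' @param ensembles named list of [rate_ensemble()]s keyed by analyte.
#' @param net a [metabolic_network()] with `analyte_map`.
#' @param at time (d) at which to take the band; defaults to the ensemble
#'   mid-horizon.
#' @param conversion unit conversion factor.
#' @return named list reaction id -> c(lb, ub).
#' @export
exchange_constraints <- function(ensembles, net, at = NULL, conversion = 1) {
  out <- list()
  for (rxn in names(net$analyte_map)) {
    a <- net$analyte_map[[rxn]]
    if (!a %in% names(ensembles)) next
    e <- ensembles[[a]]
    i <- if (is.null(at)) ceiling(length(e$times) / 2) else
      which.min(abs(e$times - at))
    out[[rxn]] <- conversion * c(e$p5[i], e$p95[i])
  }
  out
}

apply_constraints <- function(net, constraints) {
  for (rxn in names(constraints)) {
    b <- constraints[[rxn]]
    net <- set_bounds(net, rxn, lb = b[1], ub = b[2])
  }
  net
}

#' Feasibility of a constrained network
#'
#' @param net a [metabolic_network()].
#' @param constraints optional named list reaction -> c(lb, ub).
#' @return TRUE/FALSE.
#' @export
is_feasible <- function(net, constraints = NULL) {
  if (!is.null(constraints)) net <- apply_constraints(net, constraints)
  sol <- solve_lp(rep(0, ncol(net$S)), Aeq = net$S,
                  beq = rep(0, nrow(net$S)), lb = net$lb, ub = net$ub)
  sol$status == "optimal"
}

#' Resolve infeasibilities by adding demand reactions
#'
#' When the measured-rate constraints make the network infeasible, demand
#' reactions (single-metabolite sinks/sources with configured bounds) are
#' added greedily, smallest bound magnitude first, until the constrained
#' network becomes feasible.
#'
#' @param net a [metabolic_network()].
#' @param constraints named list reaction -> c(lb, ub).
#' @param demand_candidates named list: demand reaction id -> list
#'   (metabolite, lb, ub).
#' @return list with `net` (possibly extended) and `added` (ids).
#' @export
resolve_infeasibilities <- function(net, constraints,
                                    demand_candidates = list()) {
  added <- character()
  if (is_feasible(net, constraints)) {
    return(list(net = net, added = added))
  }
  ord <- order(vapply(demand_candidates, function(d) {
    max(abs(c(d$lb, d$ub)))
  }, numeric(1)))
  for (i in ord) {
    id <- names(demand_candidates)[i]
    d <- demand_candidates[[i]]
    net <- add_reaction(net, id, stats::setNames(-1, d$metabolite),
                        lb = d$lb, ub = d$ub)
    added <- c(added, id)
    if (is_feasible(net, constraints)) {
      return(list(net = net, added = added))
    }
  }
  stop("infeasible even with all candidate demand reactions; constraints: ",
       paste(names(constraints), collapse = ", "))
}

#' Identify essential exchange reactions
#'
#' An unmeasured exchange is essential iff closing it (bounds 0,0) makes
#' the constrained network infeasible. Measured exchanges are always
#' retained.
#'
#' @param net a [metabolic_network()].
#' @param measured ids of measured exchanges (always retained).
#' @param constraints applied measurement constraints.
#' @return character vector of exchanges to retain.
#' @export
essential_exchanges <- function(net, measured, constraints = NULL) {
  exch <- exchange_reactions(net)
  unmeasured <- setdiff(exch, measured)
  keep <- vapply(unmeasured, function(r) {
    closed <- set_bounds(net, r, lb = 0, ub = 0)
    !is_feasible(closed, constraints)
  }, logical(1))
  c(intersect(measured, exch), unmeasured[keep])
}

#' Prune reactions that carry no parsimonious flux under any condition
#'
#' Runs pFBA under every condition's constraints; a reaction is removable
#' iff its absolute pFBA flux is below `threshold` in all conditions.
#' Removal is verified: feasibility and the biomass optimum (1e-6 relative)
#' must be preserved under every condition, otherwise the reaction is
#' restored and logged.
#'
#' @param net a [metabolic_network()].
#' @param conditions list of constraint sets (named list rxn -> c(lb, ub));
#'   a single constraint set is promoted to one condition.
#' @param threshold zero-flux tolerance (mM/gDCW/h).
#' @param protect reaction ids never to remove (e.g. objective, pins).
#' @return list with `net`, `removed`, `restored`.
#' @export
pfba_prune <- function(net, conditions = list(list()), threshold = 1e-9,
                       protect = character()) {
  if (!is.null(names(conditions)) && length(conditions) &&
      is.numeric(conditions[[1]])) {
    conditions <- list(conditions)
  }
  protect <- union(protect, net$objective)
  ref_opt <- vapply(conditions, function(cc) {
    fba(apply_constraints(net, cc))$objective
  }, numeric(1))
  maxflux <- rep(0, ncol(net$S))
  names(maxflux) <- colnames(net$S)
  for (cc in conditions) {
    p <- pfba(apply_constraints(net, cc))
    if (p$status != "optimal") stop("pFBA infeasible under a condition")
    maxflux <- pmax(maxflux, abs(p$fluxes))
  }
  cand <- setdiff(names(maxflux)[maxflux < threshold], protect)
  removed <- character(); restored <- character()
  cur <- net
  for (r in cand) {
    trial <- remove_reactions(cur, r, drop_orphans = FALSE)
    ok <- TRUE
    for (ci in seq_along(conditions)) {
      cc <- conditions[[ci]]
      cc <- cc[setdiff(names(cc), r)]
      tc <- apply_constraints(trial, cc)
      o <- fba(tc)
      if (o$status != "optimal" ||
          abs(o$objective - ref_opt[ci]) >
            1e-6 * max(1, abs(ref_opt[ci]))) {
        ok <- FALSE; break
      }
    }
    if (ok) {
      cur <- trial
      removed <- c(removed, r)
    } else {
      restored <- c(restored, r)
    }
  }
  # drop metabolites orphaned by the accepted removals
  cur <- remove_reactions(cur, character(0), drop_orphans = TRUE)
  list(net = cur, removed = removed, restored = restored)
}

#' Detect and break thermodynamically infeasible internal cycles
#'
#' Internal cycles are flux modes that persist when every exchange is
#' closed. They are detected by flux variability analysis on the
#' exchange-closed network; cycle members are removed (lexicographically
#' smallest id whose removal preserves the growth optimum) or, when no
#' member can be removed without hurting the optimum, directionally
#' restricted.
#'
#' @param net a [metabolic_network()].
#' @param tol flux tolerance for loop detection.
#' @return list with `net`, `removed`, `restricted`.
#' @export
remove_loops <- function(net, tol = 1e-6) {
  removed <- character(); restricted <- character()
  ref <- fba(net)$objective
  repeat {
    closed <- net
    for (r in exchange_reactions(net)) {
      closed <- set_bounds(closed, r, lb = 0, ub = 0)
    }
    internal <- setdiff(colnames(net$S), exchange_reactions(net))
    rng <- fva(closed, internal)
    span <- pmax(abs(rng$min), abs(rng$max))
    span[is.na(span)] <- 0
    loopy <- internal[span > tol]
    loopy <- setdiff(loopy, net$objective)
    if (!length(loopy)) break
    fixed <- FALSE
    for (r in sort(loopy)) {
      trial <- remove_reactions(net, r, drop_orphans = FALSE)
      o <- fba(trial)
      if (o$status == "optimal" &&
          abs(o$objective - ref) <= 1e-6 * max(1, abs(ref))) {
        net <- remove_reactions(net, r, drop_orphans = TRUE)
        removed <- c(removed, r)
        fixed <- TRUE
        break
      }
    }
    if (!fixed) {
      # restrict the direction of the first loop member instead
      r <- sort(loopy)[1]
      i <- match(r, rng$reaction)
      if (rng$max[i] > tol) net <- set_bounds(net, r, ub = 0)
      else net <- set_bounds(net, r, lb = 0)
      restricted <- c(restricted, r)
      if (fba(net)$status != "optimal") {
        stop("loop removal made the network infeasible")
      }
    }
  }
  list(net = net, removed = removed, restricted = restricted)
}

#' Remove dead-end metabolites and blocked reactions
#'
#' Iterates to a fixpoint: metabolites that can only be produced or only
#' consumed (given reaction bounds) are removed together with their
#' reactions; then reactions whose flux variability range is identically
#' zero are removed.
#'
#' @param net a [metabolic_network()].
#' @param tol zero-range tolerance.
#' @param protect reaction ids never removed.
#' @return list with `net`, `removed_reactions`, `removed_metabolites`.
#' @export
prune_dead_ends <- function(net, tol = 1e-9, protect = character()) {
  protect <- union(protect, net$objective)
  rr <- character(); rm_m <- character()
  repeat {
    changed <- FALSE
    repeat {
      S <- net$S; lb <- net$lb; ub <- net$ub
      dead <- vapply(rownames(S), function(m) {
        cs <- S[m, ]
        j <- which(cs != 0)
        prod_ok <- any(cs[j] * ub[j] > tol | cs[j] * lb[j] > tol)
        cons_ok <- any(cs[j] * lb[j] < -tol | cs[j] * ub[j] < -tol)
        !(prod_ok && cons_ok)
      }, logical(1))
      if (!any(dead)) break
      mets <- rownames(S)[dead]
      rxns <- colnames(S)[colSums(S[mets, , drop = FALSE] != 0) > 0]
      rxns <- setdiff(rxns, protect)
      if (!length(rxns) && !length(mets)) break
      if (!length(rxns)) {
        # protected reactions keep the metabolite alive; stop here
        break
      }
      rm_m <- union(rm_m, mets)
      rr <- c(rr, rxns)
      net$S <- net$S[setdiff(rownames(S), mets), , drop = FALSE]
      net <- remove_reactions(net, rxns, drop_orphans = TRUE)
      changed <- TRUE
    }
    rng <- fva(net)
    blocked <- rng$reaction[is.finite(rng$min) & is.finite(rng$max) &
                              abs(rng$min) < tol & abs(rng$max) < tol]
    blocked <- setdiff(blocked, protect)
    if (length(blocked)) {
      rr <- c(rr, blocked)
      net <- remove_reactions(net, blocked, drop_orphans = TRUE)
      changed <- TRUE
    }
    if (!changed) break
  }
  net$compartments <- net$compartments[rownames(net$S)]
  list(net = net, removed_reactions = rr, removed_metabolites = rm_m)
}

#' Pin a reaction into a reduced model
#'
#' Guarantees the reaction is present in the reduced network with the given
#' bounds regardless of the pruning outcome, copying it from the source
#' (unreduced) model if needed.
#'
#' @param net the (possibly reduced) network.
#' @param source_net the unreduced network holding the reaction definition.
#' @param reaction_id reaction id.
#' @param bounds c(lb, ub) to impose.
#' @return the network with the reaction present and bounded.
#' @export
pin_reaction <- function(net, source_net, reaction_id, bounds) {
  if (!reaction_id %in% colnames(source_net$S)) {
    stop(sprintf("unknown reaction '%s' in source model", reaction_id))
  }
  if (!reaction_id %in% colnames(net$S)) {
    col <- source_net$S[, reaction_id]
    net <- add_reaction(net, reaction_id, col[col != 0],
                        lb = bounds[1], ub = bounds[2])
  } else {
    net <- set_bounds(net, reaction_id, lb = bounds[1], ub = bounds[2])
  }
  net
}

#' Stepwise network reduction pipeline
#'
#' Four top-level stages, each followed by dead-end/blocked cleanup:
#' (a) resolve infeasibilities with demand reactions, (b) identify and keep
#' only essential + measured exchanges, (c) prune reactions with no
#' parsimonious flux under any condition, (d) eliminate thermodynamically
#' infeasible cycles. Pinned reactions are reinstated at the end.
#'
#' @param net a [metabolic_network()].
#' @param conditions list of per-condition constraint sets (named list
#'   rxn -> c(lb, ub)); the first is the reference condition.
#' @param measured ids of measured exchange reactions (default: those with
#'   an analyte mapping).
#' @param demand_candidates see [resolve_infeasibilities()].
#' @param pins named list reaction id -> c(lb, ub) to pin.
#' @param pfba_threshold zero-flux threshold for stage (c).
#' @return list with `net` and `report` (a `reduction_report`).
#' @export
reduce_network <- function(net, conditions = list(list()),
                           measured = names(net$analyte_map),
                           demand_candidates = list(),
                           pins = list(), pfba_threshold = 1e-9) {
  ref_constraints <- conditions[[1]]
  report <- list()
  protect <- union(net$objective, names(pins))
  log_step <- function(name, removed, added = character()) {
    cur_feas <- is_feasible(cur, ref_constraints)
    report[[length(report) + 1L]] <<- list(
      step = name, removed = removed, added = added,
      feasible = cur_feas,
      objective = fba(apply_constraints(cur, ref_constraints))$objective,
      n_reactions = ncol(cur$S), n_metabolites = nrow(cur$S))
    if (!cur_feas) stop(sprintf("network infeasible after step '%s'", name))
  }
  # (a) feasibility resolution
  res <- resolve_infeasibilities(net, ref_constraints, demand_candidates)
  cur <- res$net
  de <- prune_dead_ends(cur, protect = protect)
  cur <- de$net
  log_step("resolve_infeasibilities",
           removed = de$removed_reactions, added = res$added)
  # (b) essential exchanges
  keep <- essential_exchanges(cur, measured, ref_constraints)
  drop <- setdiff(exchange_reactions(cur), keep)
  cur <- remove_reactions(cur, drop, drop_orphans = TRUE)
  de <- prune_dead_ends(cur, protect = protect)
  cur <- de$net
  log_step("essential_exchanges", removed = c(drop, de$removed_reactions))
  # (c) pFBA pruning
  pr <- pfba_prune(cur, conditions, threshold = pfba_threshold,
                   protect = protect)
  cur <- pr$net
  de <- prune_dead_ends(cur, protect = protect)
  cur <- de$net
  log_step("pfba_prune", removed = c(pr$removed, de$removed_reactions))
  # (d) loop removal
  lp <- remove_loops(cur)
  cur <- lp$net
  de <- prune_dead_ends(cur, protect = protect)
  cur <- de$net
  log_step("remove_loops", removed = c(lp$removed, de$removed_reactions))
  # pinned reactions reinstated
  for (id in names(pins)) {
    cur <- pin_reaction(cur, net, id, pins[[id]])
  }
  structure_report <- structure(
    list(steps = report, pinned = names(pins)),
    class = "reduction_report")
  list(net = cur, report = structure_report)
}

#' @export
print.reduction_report <- function(x, ...) {
  cat("<reduction_report>\n")
  for (s in x$steps) {
    cat(sprintf("  %-24s removed=%2d feasible=%s objective=%.6g (%d rxn, %d met)\n",
                s$step, length(s$removed), s$feasible, s$objective,
                s$n_reactions, s$n_metabolites))
  }
  if (length(x$pinned)) cat("  pinned:", paste(x$pinned, collapse = ", "),
                            "\n")
  invisible(x)
}
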