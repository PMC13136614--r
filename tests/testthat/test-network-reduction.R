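test_that("toy networks honour their structural contract", {
  base <- generate_toy_network()
  expect_lte(ncol(base$S), 30)
  expect_gte(sum(generate_toy_network()$analyte_map %in%
                   chotwin_analytes()$all), 8)
  full <- generate_toy_network(c("dead_end", "blocked",
                                 "redundant_transport",
                                 "infeasible_cycle"))
  expect_lte(ncol(full$S), 30)
  expect_identical(sum(colnames(full$S) == "DEADP"), 1L)
  expect_identical(sum(colnames(full$S) == "CYC1"), 1L)
  expect_error(generate_toy_network("typo"), "unknown pathology")
  ext <- generate_toy_network(extended_exchanges = TRUE)
  expect_length(exchange_reactions(ext), 24)
  expect_setequal(unname(ext$analyte_map),
                  setdiff(chotwin_analytes()$all, "VCD"))
})

test_that("FBA, pFBA and FVA behave on the toy network", {
  net <- generate_toy_network()
  f <- fba(net)
  expect_equal(f$objective, 25)
  expect_lt(max(abs(net$S %*% f$fluxes)), 1e-8)
  p <- pfba(net)
  expect_equal(p$objective, 25, tolerance = 1e-6)
  expect_lte(p$total_flux, sum(abs(f$fluxes)) + 1e-6)
  rng <- fva(net, c("BIOMASS", "EX_glc"))
  expect_equal(rng$max[rng$reaction == "BIOMASS"], 25, tolerance = 1e-6)
})

test_that("an over-tight exchange bound is repaired by one demand reaction", {
  net <- generate_toy_network()
  # ammonium secretion beyond what glutaminolysis can supply
  cons <- list(EX_nh4 = c(6, 10))
  expect_false(is_feasible(net, cons))
  res <- resolve_infeasibilities(
    net, cons,
    demand_candidates = list(
      DM_nh4 = list(metabolite = "nh4_c", lb = -2, ub = 0),
      DM_glu = list(metabolite = "glu_c", lb = -5, ub = 0)))
  # greedy order: smallest bound magnitude first, and it suffices
  expect_identical(res$added, "DM_nh4")
  expect_true(is_feasible(res$net, cons))
  expect_equal(unname(res$net$lb["DM_nh4"]), -2)
  expect_equal(unname(res$net$ub["DM_nh4"]), 0)
  # feasible model: no demands added
  res0 <- resolve_infeasibilities(net, list(EX_glc = c(-10, -5)))
  expect_length(res0$added, 0)
  # irreparable case: error lists the constraints
  expect_error(resolve_infeasibilities(net, list(EX_nh4 = c(50, 60)),
                                       demand_candidates = list(
                                         DM_nh4 = list(
                                           metabolite = "nh4_c",
                                           lb = -2, ub = 0))),
               "infeasible even with all candidate")
})

test_that("essential exchanges are exactly the irreplaceable ones", {
  net <- generate_toy_network()
  # demanding growth makes the sole sources of biomass precursors essential
  ess <- essential_exchanges(net, measured = c("EX_glc", "EX_gln"),
                             constraints = list(EX_glc = c(-10, -5),
                                                BIOMASS = c(1, 1000)))
  # asparagine-style auxotrophies: asp and ser have no internal source
  expect_true(all(c("EX_asp", "EX_ser") %in% ess))
  # lactate/alanine/ammonium sinks are closable
  expect_false(any(c("EX_lac", "EX_ala") %in% ess))
  # no unmeasured exchanges left: the measured set comes back unchanged
  all_ex <- exchange_reactions(net)
  expect_setequal(essential_exchanges(net, measured = all_ex), all_ex)
})

test_that("pFBA pruning respects the all-conditions rule", {
  net <- generate_toy_network("redundant_transport")
  conds <- toy_conditions()
  pr <- pfba_prune(net, conds)
  expect_true(all(c("GLCt2a", "GLCt2b") %in% pr$removed))
  # LDH carries flux in one of the two conditions -> retained
  expect_false("LDH" %in% pr$removed)
  expect_true("LDH" %in% colnames(pr$net$S))
  # infinite threshold still preserves feasibility and the optimum
  pr2 <- pfba_prune(net, conds, threshold = Inf)
  o <- fba(chotwin:::apply_constraints(pr2$net, conds[[1]]))
  ref <- fba(chotwin:::apply_constraints(net, conds[[1]]))
  expect_equal(o$objective, ref$objective, tolerance = 1e-6)
})

test_that("internal 2-cycles are detected and broken", {
  net <- generate_toy_network("infeasible_cycle")
  before <- fba(net)$objective
  rl <- remove_loops(net)
  expect_gte(length(c(rl$removed, rl$restricted)), 1)
  expect_true(any(c("CYC1", "CYC2") %in% c(rl$removed, rl$restricted)))
  expect_equal(fba(rl$net)$objective, before, tolerance = 1e-6)
  # after removal the exchange-closed internal flux space is zero
  closed <- rl$net
  for (r in exchange_reactions(closed)) {
    closed <- set_bounds(closed, r, lb = 0, ub = 0)
  }
  rng <- fva(closed, setdiff(colnames(closed$S),
                             exchange_reactions(closed)))
  span <- pmax(abs(rng$min), abs(rng$max))
  expect_lt(max(span, na.rm = TRUE), 1e-6)
  # loop-free model: no-op
  rl0 <- remove_loops(generate_toy_network())
  expect_length(c(rl0$removed, rl0$restricted), 0)
})

test_that("dead-end pruning cascades and is idempotent", {
  net <- generate_toy_network("dead_end")
  pd <- prune_dead_ends(net)
  expect_true("DEADP" %in% pd$removed_reactions)
  expect_true("dead_c" %in% pd$removed_metabolites)
  pd2 <- prune_dead_ends(pd$net)
  expect_length(pd2$removed_reactions, 0)
  # blocked-substrate reaction is removed too
  pb <- prune_dead_ends(generate_toy_network("blocked"))
  expect_true("BLKC" %in% pb$removed_reactions)
  # a clean network is untouched
  p0 <- prune_dead_ends(generate_toy_network())
  expect_length(p0$removed_reactions, 0)
})

test_that("a dead-end metabolite marks exactly its producer as blocked", {
  net <- generate_toy_network("dead_end")
  rng <- fva(net)
  blocked <- rng$reaction[abs(rng$min) < 1e-9 & abs(rng$max) < 1e-9]
  expect_identical(blocked, "DEADP")
})

test_that("pinning keeps a reaction through a full reduction", {
  net <- generate_toy_network("infeasible_cycle")
  r <- reduce_network(net, conditions = toy_conditions(),
                      pins = list(CYC1 = c(0, 0)))
  expect_true("CYC1" %in% colnames(r$net$S))
  expect_equal(unname(r$net$lb["CYC1"]), 0)
  expect_equal(unname(r$net$ub["CYC1"]), 0)
  # pinning an unknown reaction is a lookup error
  expect_error(pin_reaction(r$net, net, "NOPE", c(0, 1)),
               "unknown reaction")
})

test_that("the full pipeline resolves every pathology and preserves the optimum", {
  base <- generate_toy_network()
  conds <- toy_conditions()
  r0 <- reduce_network(base, conditions = conds)
  expect_identical(sum(vapply(r0$report$steps,
                              function(s) length(s$removed), 1L)), 0L)
  expect_identical(r0$net$S, base$S)
  expect_identical(r0$net$lb, base$lb)
  expect_length(r0$report$steps, 4)
  full <- generate_toy_network(c("dead_end", "blocked",
                                 "redundant_transport",
                                 "infeasible_cycle"))
  r <- reduce_network(full, conditions = conds)
  expect_true(all(vapply(r$report$steps, `[[`, TRUE, "feasible")))
  expect_length(intersect(c("DEADP", "BLKC", "GLCt2a", "GLCt2b", "CYC1",
                            "CYC2"), colnames(r$net$S)), 0)
  o_full <- fba(chotwin:::apply_constraints(full, conds[[1]]))$objective
  o_red <- fba(chotwin:::apply_constraints(r$net, conds[[1]]))$objective
  expect_equal(o_red, o_full, tolerance = 1e-6)
  expect_lte(ncol(r$net$S), ncol(full$S))
  expect_lte(nrow(r$net$S), nrow(full$S))
  # determinism
  r2 <- reduce_network(full, conditions = conds)
  expect_identical(r$net$S, r2$net$S)
})

test_that("rate ensembles map onto exchange constraint bands", {
  b <- fx_batch_clean()
  ens <- truth_rate_ensembles(b, times = 0:14, n_traj = 20, seed = 3)
  net <- generate_toy_network()
  cons <- exchange_constraints(ens, net, at = 7)
  expect_true(all(names(cons) %in% names(net$analyte_map)))
  for (r in names(cons)) {
    expect_lte(cons[[r]][1], cons[[r]][2])
  }
  # conversion scales linearly
  cons2 <- exchange_constraints(ens, net, at = 7, conversion = 2)
  expect_equal(cons2[["EX_glc"]], 2 * cons[["EX_glc"]])
})
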