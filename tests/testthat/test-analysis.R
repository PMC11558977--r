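test_that("energy cost and oxphos share follow their definitions", {
  # one ATP-producing reaction with E = 0.01 and v_ATP = 2 -> cost 0.005
  mets <- rbind(metabolite("a_c"), metabolite("atp_c"), metabolite("adp_c"))
  rxns <- list(
    reaction("SRC", c(a_c = 1), 0, 10),
    reaction("MAKE_ATP", c(a_c = -1, adp_c = -2, atp_c = 2), gpr = "g1"),
    reaction("ATPM", c(atp_c = -1, adp_c = 1)),
    reaction("BIO", c(atp_c = -2, adp_c = 2)))
  m <- metabolic_model(mets, rxns, objective = "BIO")
  # choose kcat so that at v = 1 the usage is exactly 0.01 g/gDW
  e <- enzyme_entry("MAKE_ATP",
                    data.frame(gene_id = "g1", subunit_count = 1,
                               subunit_mw = 36), kcat = 36 / (0.5 * 0.01 * 3600))
  ec <- build_ec_model(m, list(MAKE_ATP = e), ptot = 0.4653, f = 0.55)
  ec <- set_bounds(ec, "SRC", lb = 1, ub = 1)
  scan <- adjustment_scan(ec, "SRC", uptake_rates = 1, substrate_mw = 0.18,
                          atp_metabolite_id = "atp_c",
                          oxphos_reaction_ids = "MAKE_ATP",
                          overflow_exchange_ids = character(0))
  expect_equal(scan$energy_cost, 0.01 / 2)
  expect_equal(scan$oxphos_ratio, 1)   # all ATP from the designated reaction
})

test_that("hierarchy ordering applies strict dominance and co-utilization", {
  prec <- paste0("p", 1:12)
  eff <- matrix(0, 3, 12, dimnames = list(c("a", "b", "d"), prec))
  eff["a", ] <- 10
  eff["b", ] <- 5
  eff["d", ] <- 1
  h <- hierarchy_order(eff)
  expect_identical(h$tiers, list("a", "b", "d"))
  expect_identical(
    h$dominance$verdict[h$dominance$first == "a" & h$dominance$second == "b"],
    "first_preferred")
  # mixed dominance (10 vs 2 precursors) means co-utilization
  eff2 <- eff
  eff2["b", 1:2] <- 20
  h2 <- hierarchy_order(eff2)
  expect_identical(
    h2$dominance$verdict[h2$dominance$first == "a" & h2$dominance$second == "b"],
    "co_utilized")
  expect_identical(h2$tiers[[1]], c("a", "b"))
  # a tie on any precursor blocks strict dominance
  eff3 <- eff
  eff3["b", 1] <- 10
  h3 <- hierarchy_order(eff3)
  expect_identical(
    h3$dominance$verdict[h3$dominance$first == "a" & h3$dominance$second == "b"],
    "co_utilized")
  expect_error(hierarchy_order(eff - 100), "non-negative")
})

test_that("precursor efficiency is scale-invariant and flags dead ends", {
  mk <- minicore_fixture()
  res <- precursor_efficiency(mk$ec_closed, "EX_glc", 6,
                              c("pyr_c", "aral_c"), carbon_uptake = 15)
  pyr <- res[res$precursor == "pyr_c", ]
  expect_equal(pyr$epsilon, pyr$flux / pyr$e_min)
  # doubling flux and E_min leaves the ratio unchanged
  expect_equal((2 * pyr$flux) / (2 * pyr$e_min), pyr$epsilon)
  # the arabitol intermediate is unreachable from glucose
  ara <- res[res$precursor == "aral_c", ]
  expect_identical(ara$flag, "unreachable")
  expect_equal(ara$epsilon, 0)
  expect_error(precursor_efficiency(mk$ec_closed, "EX_glc", 6, "ghost_c"),
               "unknown precursor")
})

test_that("carbon-equal uptake bounds follow from the carbon counts", {
  mk <- minicore_fixture()
  subs <- mk$config$substrates
  bounds <- 15 / subs$carbon_count
  expect_equal(bounds, c(2.5, 1.25, 3, 2.5, 3))
})

test_that("top-cost targets are ranked by per-gene enzyme cost", {
  mk <- minicore_fixture()
  rep <- targets_top_cost(mk$ec_closed, "EX_etoh",
                          conditions = list(EX_glc = 3), n = 2)
  expect_lte(nrow(rep), 2)
  expect_true(all(diff(rep$score) <= 1e-12))
  expect_true(all(rep$direction == "enhance"))
  # n larger than the gene count returns everything that carries cost
  rep_all <- targets_top_cost(mk$ec_closed, "EX_etoh",
                              conditions = list(EX_glc = 3), n = 1000)
  expect_lt(nrow(rep_all), length(mk$ec$base$reactions))
  expect_identical(rep$identifier, rep_all$identifier[1:nrow(rep)])
  # complexes split cost among member genes by subunit mass share
  usage <- stats::setNames(0.02, "OXPHOS")
  gc <- ecflux:::gene_costs(mk$ec, usage)
  expect_equal(sum(gc[c("nd1", "nd2", "atps")]), 0.02)
  expect_equal(unname(gc[["nd1"]]), 0.02 * 400 / 1000)
})

test_that("HGLP/LGHP classification uses the flux threshold and cost sign", {
  mk <- minicore_fixture()
  rep <- targets_hglp_lghp(mk$ec_closed, "EX_etoh",
                           conditions = list(EX_glc = 3), flux_threshold = 1)
  expect_true(all(pmax(rep$flux_hglp, rep$flux_lghp) > 1))
  enh <- rep$identifier[rep$direction == "enhance"]
  wk <- rep$identifier[rep$direction == "weaken"]
  expect_true(all(rep$cost_lghp[rep$identifier %in% enh & rep$cost_hglp > 0] >=
                  rep$cost_hglp[rep$identifier %in% enh & rep$cost_hglp > 0]))
  # sub-threshold reactions are excluded
  expect_false("PGM" %in% rep$identifier)
  expect_true(length(intersect(c("PDC", "ADH"), enh)) == 2)
  expect_true("OXPHOS" %in% wk)
})
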