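test_that("FBA respects bounds and the enzyme pool row", {
  m <- chain_model(src_ub = 10)
  expect_equal(fba(m)$objective_value, 10)
  # pool coefficient 0.002 on the conversion step, pool bound 0.01 -> optimum 5
  e <- enzyme_entry("CONV", data.frame(gene_id = "g1", subunit_count = 1,
                                       subunit_mw = 36), kcat = 10)
  ec <- build_ec_model(m, list(CONV = e), ptot = 0.02, f = 0.5)
  sol <- fba(ec)
  expect_equal(sol$objective_value, 5)
  expect_equal(sol$pool_utilization, 1, tolerance = 1e-6)
  # ec-constrained optimum never exceeds the unconstrained one
  mk <- minicore_fixture()
  ec10 <- set_uptake(mk$ec_closed, "EX_glc", 10)
  un10 <- set_uptake(mk$base_split_closed, "EX_glc", 10)
  expect_lte(fba(ec10)$objective_value, fba(un10)$objective_value + 1e-9)
  # status reporting, not exceptions
  blocked <- set_bounds(m, "SINK", lb = 20, ub = 30)
  expect_identical(fba(blocked)$status, "infeasible")
})

test_that("pFBA keeps the FBA optimum and routes flux parsimoniously", {
  m <- parallel_model()
  sol <- pfba(m)
  expect_equal(sol$objective_value, 10)
  expect_equal(unname(sol$fluxes[["FAST"]]), 10)
  expect_equal(unname(sol$fluxes[["SLOW1"]]), 0)
  mk <- minicore_fixture()
  ec3 <- set_uptake(mk$ec_closed, "EX_glc", 3)
  expect_equal(pfba(ec3)$objective_value, fba(ec3)$objective_value,
               tolerance = 1e-9)
})

test_that("pFBA total flux beats alternative optima from perturbed objectives", {
  mk <- minicore_fixture()
  ec3 <- set_uptake(mk$ec_closed, "EX_glc", 3)
  psol <- pfba(ec3)
  lp <- ecflux:::as_lp(ec3)
  lb <- lp$lb; ub <- lp$ub
  lb[match("BIOMASS", lp$rxns)] <- psol$objective_value
  set.seed(7)
  for (i in 1:20) {
    w <- runif(length(lp$rxns))
    alt <- ecflux:::solve_lp(w, Aeq = lp$S, beq = rep(0, nrow(lp$S)),
                             Ale = matrix(lp$pool, 1), ble = lp$pool_bound,
                             lb = lb, ub = ub, maximize = FALSE)
    expect_identical(alt$status, "optimal")
    expect_lte(sum(psol$fluxes), sum(alt$x) + 1e-9)
  }
})

test_that("minimum-enzyme solutions pick the cheapest route and grow with demand", {
  # parallel routes with equal MW/sigma, kcats 10 vs 100: all flux on the
  # fast route, E_min = MW / (0.5 * 100 * 3600)
  mets <- rbind(metabolite("a_c"), metabolite("b_c"))
  rxns <- list(reaction("SRC", c(a_c = 1), 0, 10),
               reaction("SLOW", c(a_c = -1, b_c = 1), 0, 1000, gpr = "gs"),
               reaction("FASTR", c(a_c = -1, b_c = 1), 0, 1000, gpr = "gf"),
               reaction("SINK", c(b_c = -1), 0, 1000))
  m <- metabolic_model(mets, rxns, objective = "SINK")
  cx <- function(g) data.frame(gene_id = g, subunit_count = 1, subunit_mw = 36)
  ec <- build_ec_model(m, list(SLOW = enzyme_entry("SLOW", cx("gs"), 10),
                               FASTR = enzyme_entry("FASTR", cx("gf"), 100)),
                       ptot = 0.4653, f = 0.55)
  sol <- min_enzyme_solution(ec, c(SINK = 1))
  expect_equal(sol$objective_value, 36 / (0.5 * 100 * 3600))
  expect_equal(unname(sol$fluxes[["SLOW"]]), 0)
  expect_equal(min_enzyme_solution(ec, c(SINK = 0))$objective_value, 0)
  # E_min non-decreasing in the fixed demand
  mk <- minicore_fixture()
  ec2 <- set_uptake(mk$ec_closed, "EX_glc", 3)
  levels <- seq(0.05, 0.25, length.out = 5)
  emins <- vapply(levels, function(b)
    min_enzyme_solution(ec2, c(BIOMASS = b))$objective_value, numeric(1))
  expect_true(all(diff(emins) > -1e-9))
})

test_that("raw FVA collapses on a forced chain and matches bounds logic", {
  m <- chain_model(src_ub = 10)
  raw <- fva_raw(m)
  expect_true(all(abs(raw$v_max - raw$v_min) < 1e-9))
  expect_true(all(abs(raw$v_max - 10) < 1e-9))
  # a reaction in a dead-end branch is pinned to zero
  mets <- rbind(metabolite("a_c"), metabolite("b_c"), metabolite("d_c"))
  rxns <- list(reaction("SRC", c(a_c = 1), 0, 10),
               reaction("CONV", c(a_c = -1, b_c = 1)),
               reaction("DEAD", c(a_c = -1, d_c = 1)),
               reaction("SINK", c(b_c = -1)))
  m2 <- metabolic_model(mets, rxns, objective = "SINK")
  raw2 <- fva_raw(m2, "DEAD", fraction_of_optimum = 0)
  expect_equal(raw2$v_min, 0)
  expect_equal(raw2$v_max, 0)
})

test_that("variability aggregation applies the isozyme and reverse rules", {
  sm <- ecflux:::new_split_map(
    forward_of = list(ISO = "ISO", REV = "REV", PLAIN = "PLAIN"),
    reverse_of = list(REV = "REV_reverse"),
    isozyme_copies = list(ISO = c("ISO_num1", "ISO_num2"), REV = "REV",
                          REV_reverse = "REV_reverse", PLAIN = "PLAIN"))
  raw <- data.frame(
    reaction_id = c("ISO_num1", "ISO_num2", "REV", "REV_reverse", "PLAIN"),
    v_min = c(0, 0, 0, 0, 1),
    v_max = c(3, 5, 5, 2, 4))
  agg <- aggregate_variability(raw, sm)
  fv <- stats::setNames(agg$fv, agg$reaction_id)
  expect_equal(fv[["ISO"]], 5)      # max over isozyme copies
  expect_equal(fv[["REV"]], 3)      # forward range minus reverse range
  expect_equal(fv[["PLAIN"]], 3)    # degenerate single-copy case
  # negative differences clamp to zero
  raw$v_max[raw$reaction_id == "REV_reverse"] <- 7
  expect_message(agg2 <- aggregate_variability(raw, sm), "clamped")
  expect_equal(agg2$fv[agg2$reaction_id == "REV"], 0)
  # net-flux alternative adds the directional ranges
  agg3 <- aggregate_variability(raw, sm, rule = "net")
  expect_equal(agg3$fv[agg3$reaction_id == "REV"], 5 + 7)
  expect_error(aggregate_variability(raw[-1, ], sm), "missing")
})

test_that("PhPP grids have the right shape, zero column and monotonicity", {
  mk <- minicore_fixture()
  grid <- phpp(mk$ec_closed, "EX_glc", c(0, 10), "EX_o2", c(0, 50),
               steps = c(6, 5))
  expect_identical(dim(grid), c(6L, 5L))
  expect_true(all(grid[1, ] == 0))   # no substrate, no growth
  expect_true(all(grid[, 1] == 0))   # fully anaerobic minicore cannot grow
  # growth non-decreasing in each uptake bound
  expect_true(all(apply(grid, 2, function(col) all(diff(col) > -1e-9))))
  expect_true(all(apply(grid, 1, function(row) all(diff(row) > -1e-9))))
  expect_error(phpp(mk$ec_closed, "EX_nope", c(0, 1), "EX_o2", c(0, 1), 3),
               "unknown exchange")
})

test_that("the optimum responds monotonically to kcats and pool size", {
  mk <- minicore_fixture()
  ec <- set_uptake(mk$ec_closed, "EX_glc", 4)   # pool-limited regime
  base_mu <- fba(ec)$objective_value
  for (rid in c("OXPHOS", "GLCup", "PDH")) {
    up <- ec; up$enzymes[[rid]]$kcat <- up$enzymes[[rid]]$kcat * 2
    dn <- ec; dn$enzymes[[rid]]$kcat <- dn$enzymes[[rid]]$kcat * 0.5
    expect_gte(fba(up)$objective_value, base_mu - 1e-9)
    expect_lte(fba(dn)$objective_value, base_mu + 1e-9)
  }
  bigger <- ec; bigger$pool_bound <- ec$pool_bound * 1.5
  smaller <- ec; smaller$pool_bound <- ec$pool_bound * 0.5
  expect_gte(fba(bigger)$objective_value, base_mu - 1e-9)
  expect_lte(fba(smaller)$objective_value, base_mu + 1e-9)
  # removing the pool row reproduces the unconstrained optimum
  nopool <- ec; nopool$pool_bound <- Inf
  un <- set_uptake(mk$base_split_closed, "EX_glc", 4)
  expect_equal(fba(nopool)$objective_value, fba(un)$objective_value,
               tolerance = 1e-9)
})
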