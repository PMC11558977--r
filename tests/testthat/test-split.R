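test_that("reversible splitting follows the bound convention and is idempotent", {
  mets <- rbind(metabolite("a_c"), metabolite("b_c"))
  rxns <- list(
    reaction("SRC", c(a_c = 1), 0, 10),
    reaction("REV", c(a_c = -1, b_c = 1), -10, 20, gpr = "g1"),
    reaction("SINK", c(b_c = -1), 0, 1000))
  m <- metabolic_model(mets, rxns, objective = "SINK")
  sp <- to_irreversible(m)
  r <- sp$model$reactions
  expect_equal(r$REV$lower_bound, 0)
  expect_equal(r$REV$upper_bound, 20)
  expect_equal(r$REV_reverse$lower_bound, 0)
  expect_equal(r$REV_reverse$upper_bound, 10)
  expect_equal(r$REV_reverse$stoichiometry, c(a_c = 1, b_c = -1))
  expect_identical(sp$split_map$reverse_of$REV, "REV_reverse")
  # irreversible reactions pass through
  expect_null(sp$split_map$reverse_of$SRC)
  expect_equal(r$SRC, m$reactions$SRC)
  # idempotence
  sp2 <- to_irreversible(sp$model)
  expect_identical(names(sp2$model$reactions), names(sp$model$reactions))
  expect_equal(sp2$model, sp$model)
})

test_that("isozyme expansion creates one copy per conjunct, in order", {
  mets <- rbind(metabolite("a_c"), metabolite("b_c"))
  rxns <- list(
    reaction("SRC", c(a_c = 1), 0, 10),
    reaction("ISO", c(a_c = -1, b_c = 1), 0, 50, gpr = "(g1 and g2) or g3"),
    reaction("SINK", c(b_c = -1), 0, 1000))
  m <- metabolic_model(mets, rxns, objective = "SINK")
  sp <- expand_isozymes(m)
  r <- sp$model$reactions
  expect_setequal(sp$split_map$isozyme_copies$ISO, c("ISO_num1", "ISO_num2"))
  expect_identical(gpr_genes(r$ISO_num1$gpr), c("g1", "g2"))
  expect_identical(r$ISO_num2$gpr, "g3")
  expect_equal(r$ISO_num1$stoichiometry, m$reactions$ISO$stoichiometry)
  expect_equal(r$ISO_num1$upper_bound, 50)
  # single-gene rules untouched; expansion idempotent
  expect_identical(names(expand_isozymes(sp$model)$model$reactions), names(r))
})

test_that("splitting preserves the FBA optimum and net-flux feasibility", {
  mk <- minicore_fixture()
  orig <- set_uptake(mk$base, "EX_glc", 5)
  for (ex in setdiff(mk$config$substrates$exchange_id, "EX_glc"))
    orig <- set_uptake(orig, ex, 0)
  sp <- split_model(orig)
  f_orig <- fba(orig)
  f_split <- fba(sp$model)
  expect_equal(f_orig$objective_value, f_split$objective_value,
               tolerance = 1e-9)
  # mapping split fluxes back gives a mass-balanced original flux vector
  net <- net_fluxes(f_split$fluxes, sp$split_map)
  S <- stoich_matrix(orig)
  expect_lt(max(abs(S %*% net[colnames(S)])), 1e-6)
  bnds <- cbind(vapply(orig$reactions, `[[`, numeric(1), "lower_bound"),
                vapply(orig$reactions, `[[`, numeric(1), "upper_bound"))
  expect_true(all(net >= bnds[, 1] - 1e-6 & net <= bnds[, 2] + 1e-6))
})

test_that("net_fluxes sums isozyme copies and subtracts reverse flux", {
  sm <- ecflux:::new_split_map(
    forward_of = list(R1 = "R1", R2 = "R2"),
    reverse_of = list(R1 = "R1_reverse"),
    isozyme_copies = list(R1 = "R1", R1_reverse = "R1_reverse",
                          R2 = c("R2_num1", "R2_num2")))
  fx <- c(R1 = 5, R1_reverse = 2, R2_num1 = 1.5, R2_num2 = 0.5)
  net <- net_fluxes(fx, sm)
  expect_equal(net[["R1"]], 3)
  expect_equal(net[["R2"]], 2)
  expect_equal(unname(net_fluxes(fx * 0, sm)), c(0, 0))
  expect_error(net_fluxes(c(fx, BOGUS = 1), sm), "unknown split ids")
})
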