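test_that("enzyme mass fraction is the model share of proteome mass", {
  prot <- data.frame(protein_id = c("p1", "p2"),
                     abundance_mole_ratio = c(1, 1),
                     mw_kda = c(10, 30))
  expect_equal(enzyme_mass_fraction(prot, "p1"), 0.25)
  expect_equal(enzyme_mass_fraction(prot, c("p1", "p2")), 1)
  expect_equal(enzyme_mass_fraction(prot, character(0)), 0)
  expect_error(enzyme_mass_fraction(prot[0, ], "p1"), "empty")
  # proteins absent from the table are excluded from the numerator
  expect_message(f <- enzyme_mass_fraction(prot, c("p1", "ghost")), "absent")
  expect_equal(f, 0.25)
})

test_that("complex molecular weight sums subunit counts times subunit MWs", {
  homodimer <- data.frame(gene_id = "g", subunit_count = 2, subunit_mw = 50)
  expect_equal(assemble_mw(homodimer), 100)
  hetero <- data.frame(gene_id = c("g1", "g2"), subunit_count = c(2, 1),
                       subunit_mw = c(50, 30))
  expect_equal(assemble_mw(hetero), 130)
  missing_count <- data.frame(gene_id = "g", subunit_count = NA,
                              subunit_mw = 50)
  expect_message(mw <- assemble_mw(missing_count), "defaulting to 1")
  expect_equal(mw, 50)
  expect_error(assemble_mw(hetero[0, ]), "empty")
})

test_that("kcat merging honors source priority, fallback keys and imputation", {
  rec <- data.frame(
    reaction_id = c("R1", "R1", "R2", "R3"),
    kcat_s = c(5, 7, 1, 100),
    source = c("turnup_predicted", "database", "database", "database"),
    stringsAsFactors = FALSE)
  out <- merge_kcat(rec, reactions = c("R1", "R2", "R3"))
  expect_equal(out$kcat_s[out$reaction_id == "R1"], 7)  # database outranks
  # median imputation for uncovered reactions
  out2 <- merge_kcat(rec, reactions = c("R1", "R2", "R3", "R4"))
  r4 <- out2[out2$reaction_id == "R4", ]
  expect_equal(r4$kcat_s, stats::median(c(7, 1, 100)))
  expect_identical(r4$source, "imputed")
  # imputation = none leaves the reaction uncovered
  out3 <- merge_kcat(rec, reactions = c("R1", "R4"), imputation = "none")
  expect_identical(out3$reaction_id, "R1")
  # a record keyed by the original id applies to split copies
  out4 <- merge_kcat(rec, reactions = c("R1_num2", "R1_reverse_num1"))
  expect_equal(out4$kcat_s, c(7, 7))
  expect_error(merge_kcat(rec[0, ], reactions = "R1"), "no kcat records")
  bad <- rec; bad$source[1] <- "guessed"
  expect_error(merge_kcat(bad, reactions = "R1"), "not covered")
})

test_that("pool bound and coefficients follow the mass-balance units", {
  mk <- minicore_fixture()
  expect_equal(mk$ec$pool_bound, 0.4653 * 0.55)
  expect_equal(mk$ec$pool_bound, 0.255915)
  # MW 36 kDa, sigma 0.5, kcat 10 /s -> 36 / (0.5 * 36000) = 0.002 g.h/mmol
  e <- enzyme_entry("R1", data.frame(gene_id = "g", subunit_count = 1,
                                     subunit_mw = 36), kcat = 10, sigma = 0.5)
  expect_equal(e$assembled_mw / (e$sigma * e$kcat * 3600), 0.002)
  # reactions without enzyme data have zero pool coefficient
  coefs <- pool_coefficients(mk$ec)
  expect_equal(unname(coefs["BIOMASS"]), 0)
  expect_equal(unname(coefs["ATPM"]), 0)
  expect_true(all(coefs[names(mk$ec$enzymes)] > 0))
})

test_that("enzyme usage is v * MW / (sigma * kcat * 3600) and binds at optimum", {
  e <- enzyme_entry("R1", data.frame(gene_id = "g", subunit_count = 2,
                                     subunit_mw = 50), kcat = 10, sigma = 0.5)
  mets <- rbind(metabolite("a_c"))
  rxns <- list(reaction("SRC", c(a_c = 1), 0, 10),
               reaction("R1", c(a_c = -1), 0, 1000, gpr = "g"))
  m <- metabolic_model(mets, rxns, objective = "R1")
  ec <- build_ec_model(m, list(R1 = e), ptot = 0.4653, f = 0.55)
  u <- enzyme_usage(ec, c(SRC = 1, R1 = 1))
  expect_equal(unname(u$usage[["R1"]]), 100 / 18000)
  expect_equal(u$total, 100 / 18000)
  expect_equal(enzyme_usage(ec, c(SRC = 0, R1 = 0))$total, 0)
  expect_error(enzyme_usage(ec, c(SRC = 1, R1 = -1)), "negative flux")

  # at saturating substrate the pool constraint binds at the FBA optimum
  mk <- minicore_fixture()
  ec_sat <- set_uptake(mk$ec_closed, "EX_glc", 1000)
  sol <- fba(ec_sat)
  slack <- mk$ec$pool_bound - enzyme_usage(mk$ec, pmax(sol$fluxes, 0))$total
  expect_lt(abs(slack), 1e-6)
})

test_that("build_ec_model validates its inputs", {
  mk <- minicore_fixture()
  sp <- split_model(mk$base)
  entries <- make_enzyme_entries(sp$model, mk$kcat_table, mk$subunit_table)
  expect_error(build_ec_model(mk$base, entries), "irreversible")
  expect_error(build_ec_model(sp$model, entries, ptot = 0), "positive")
  bogus <- entries
  names(bogus)[1] <- "NOT_A_REACTION"
  bogus[[1]]$reaction_id <- "NOT_A_REACTION"
  expect_error(build_ec_model(sp$model, bogus), "unknown reaction")
})
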