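test_that("validate_model reports each class of finding", {
  mk <- minicore_fixture()
  expect_identical(validate_model(mk$base), character(0))

  m <- mk$base
  m$metabolites <- rbind(m$metabolites, m$metabolites[1, ])
  expect_match(validate_model(m), "duplicate metabolite", all = FALSE)

  m2 <- mk$base
  m2$reactions$PGI$lower_bound <- 5
  m2$reactions$PGI$upper_bound <- 2
  expect_match(validate_model(m2), "lower_bound > upper_bound", all = FALSE)

  m3 <- mk$base
  m3$reactions$PGI$stoichiometry <- c(ghost_c = -1, f6p_c = 1)
  expect_match(validate_model(m3), "undeclared metabolite", all = FALSE)

  m4 <- mk$base
  m4$objective <- "NOPE"
  expect_match(validate_model(m4), "objective", all = FALSE)

  m5 <- mk$base
  m5$metabolites$carbon_count[m5$metabolites$id == "glc_e"] <- 5L
  expect_match(validate_model(m5), "carbon_count", all = FALSE)
})

test_that("carbon counting follows the chemical formula", {
  expect_identical(count_carbons("C6H12O6"), 6L)
  expect_identical(count_carbons("C12H22O11"), 12L)
  expect_identical(count_carbons("H2O"), 0L)
  # 'C' followed by lowercase is a different element
  expect_identical(count_carbons("CaCl2"), 0L)
  expect_identical(count_carbons("CH3COOH"), 2L)
})

test_that("COBRA JSON round-trips field-for-field", {
  mk <- minicore_fixture()
  path <- withr::local_tempfile(fileext = ".json")
  write_model(mk$base, path)
  back <- read_model(path)
  expect_equal(back$metabolites, mk$base$metabolites)
  expect_equal(back$genes, mk$base$genes)
  expect_identical(back$objective, mk$base$objective)
  expect_identical(names(back$reactions), names(mk$base$reactions))
  for (id in names(back$reactions)) {
    a <- back$reactions[[id]]; b <- mk$base$reactions[[id]]
    expect_identical(sort(names(a$stoichiometry)), sort(names(b$stoichiometry)))
    expect_equal(a$stoichiometry[names(b$stoichiometry)], b$stoichiometry)
    expect_equal(a$lower_bound, b$lower_bound)
    expect_equal(a$upper_bound, b$upper_bound)
    expect_identical(gpr_to_dnf(a$gpr), gpr_to_dnf(b$gpr))
  }
  # write-read-write is byte-stable
  path2 <- withr::local_tempfile(fileext = ".json")
  write_model(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("SBML round-trips bounds, GPRs and the objective", {
  mk <- minicore_fixture()
  path <- withr::local_tempfile(fileext = ".xml")
  write_model(mk$base, path, format = "sbml")
  back <- read_model(path, format = "sbml")
  expect_identical(names(back$reactions), names(mk$base$reactions))
  expect_identical(back$objective, mk$base$objective)
  for (id in names(back$reactions)) {
    a <- back$reactions[[id]]; b <- mk$base$reactions[[id]]
    expect_equal(a$lower_bound, b$lower_bound, info = id)
    expect_equal(a$upper_bound, b$upper_bound, info = id)
    expect_equal(a$stoichiometry[names(b$stoichiometry)], b$stoichiometry)
    expect_identical(gpr_to_dnf(a$gpr), gpr_to_dnf(b$gpr), info = id)
  }
  # same optimum through either serialization
  expect_equal(fba(back)$objective_value, fba(mk$base)$objective_value,
               tolerance = 1e-9)
})

test_that("malformed and invalid files are rejected with useful errors", {
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", bad)
  expect_error(read_model(bad), "malformed")

  dangling <- withr::local_tempfile(fileext = ".json")
  writeLines('{
    "metabolites": [{"id": "a_c"}],
    "reactions": [{"id": "R1", "metabolites": {"ghost_c": -1},
                   "lower_bound": 0, "upper_bound": 10,
                   "objective_coefficient": 1}],
    "genes": []}', dangling)
  expect_error(read_model(dangling), "undeclared metabolite")

  expect_error(read_model(tempfile()), "not found")
})

test_that("ecModel serialization preserves enzymes and pool parameters", {
  mk <- minicore_fixture()
  path <- withr::local_tempfile(fileext = ".json")
  write_ec_model(mk$ec, path)
  back <- read_ec_model(path)
  expect_equal(back$ptot, mk$ec$ptot)
  expect_equal(back$f, mk$ec$f)
  expect_equal(back$pool_bound, mk$ec$pool_bound)
  expect_setequal(names(back$enzymes), names(mk$ec$enzymes))
  for (id in names(back$enzymes)) {
    expect_equal(back$enzymes[[id]]$kcat, mk$ec$enzymes[[id]]$kcat)
    expect_equal(back$enzymes[[id]]$assembled_mw, mk$ec$enzymes[[id]]$assembled_mw)
    expect_equal(back$enzymes[[id]]$sigma, mk$ec$enzymes[[id]]$sigma)
  }
  expect_equal(fba(back)$objective_value, fba(mk$ec)$objective_value,
               tolerance = 1e-9)
})
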