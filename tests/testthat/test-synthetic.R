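test_that("the minicore generator is deterministic and valid", {
  a <- make_minicore()
  b <- make_minicore()
  fa <- withr::local_tempfile(fileext = ".json")
  fb <- withr::local_tempfile(fileext = ".json")
  write_model(a$model, fa)
  write_model(b$model, fb)
  expect_identical(readLines(fa), readLines(fb))
  expect_identical(a$kcat_table, b$kcat_table)
  expect_identical(validate_model(a$model), character(0))
  # every enzymatic reaction of the split model carries an enzyme entry
  mk <- minicore_fixture()
  enzymatic <- names(Filter(function(r) nzchar(r$gpr), mk$ec$base$reactions))
  expect_setequal(names(mk$ec$enzymes), enzymatic)
})

test_that("random toys are reproducible, distinct across seeds, and feasible", {
  t1 <- make_random_toy(8, 14, seed = 3)
  t2 <- make_random_toy(8, 14, seed = 3)
  expect_identical(t1, t2)
  t3 <- make_random_toy(8, 14, seed = 4)
  expect_false(identical(t1, t3))
  expect_error(make_random_toy(2, 5, seed = 1), "n_reactions >= n_metabolites")
  for (seed in 1:50) {
    toy <- make_random_toy(6, 10, seed = seed)
    expect_identical(validate_model(toy), character(0))
    sol <- fba(toy)
    expect_identical(sol$status, "optimal")
    expect_gt(sol$objective_value, 0)
  }
})

test_that("synthetic proteomes plant the enzyme mass fraction exactly", {
  mk <- minicore_fixture()
  for (seed in 1:20) {
    sp <- synth_proteome(mk$base, planted_f = 0.55, n_extra_proteins = 40,
                         seed = seed)
    f <- enzyme_mass_fraction(sp$proteome, sp$ground_truth$model_protein_ids)
    expect_equal(f, 0.55, tolerance = 1e-12)
  }
  sp1 <- synth_proteome(mk$base, planted_f = 1, n_extra_proteins = 0, seed = 1)
  expect_equal(enzyme_mass_fraction(sp1$proteome,
                                    sp1$ground_truth$model_protein_ids), 1)
  expect_error(synth_proteome(mk$base, planted_f = 1, n_extra_proteins = 5),
               "inconsistent")
})

test_that("kcat perturbation records ground truth and factor 1 is identity", {
  mk <- minicore_fixture()
  pert <- perturb_kcats(mk$ec, 0.2)
  orig <- vapply(mk$ec$enzymes, `[[`, numeric(1), "kcat")
  expect_equal(pert$ground_truth$original_kcats, orig)
  after <- vapply(pert$model$enzymes, `[[`, numeric(1), "kcat")
  expect_equal(after, orig * 0.2)
  same <- perturb_kcats(mk$ec, 1)
  expect_equal(vapply(same$model$enzymes, `[[`, numeric(1), "kcat"), orig)
  expect_error(perturb_kcats(mk$ec, 2, subset = "BOGUS"), "no enzyme entry")
})

test_that("synthetic 13C tables are deterministic and noise-free at cv = 0", {
  mk <- minicore_fixture()
  cond <- list(EX_glc = 2)
  t1 <- synth_c13_fluxes(mk$ec_closed, mk$split_map,
                         mk$config$c13_reaction_ids, cond, noise_cv = 0)
  sol <- pfba(apply_conditions(mk$ec_closed, cond))
  net <- net_fluxes(sol$fluxes, mk$split_map)
  expect_equal(t1$flux_mmol_gdw_h, unname(net[t1$reaction_id]))
  expect_equal(unique(t1$rel_tolerance), 0.05)
  t2 <- synth_c13_fluxes(mk$ec_closed, mk$split_map,
                         mk$config$c13_reaction_ids, cond,
                         noise_cv = 0.1, seed = 9)
  t3 <- synth_c13_fluxes(mk$ec_closed, mk$split_map,
                         mk$config$c13_reaction_ids, cond,
                         noise_cv = 0.1, seed = 9)
  expect_identical(t2, t3)
  expect_false(identical(t1$flux_mmol_gdw_h, t2$flux_mmol_gdw_h))
  expect_equal(unique(t2$rel_tolerance), 0.2)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(make_random_toy(5, 8, seed = 42))
  invisible(synth_proteome(minicore_fixture()$base, seed = 42))
  after <- runif(1)
  expect_identical(before, after)
})
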