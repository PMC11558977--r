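# The "minicore" fixture: a small, fully determined central-carbon network
# engineered to exhibit the phenomena enzyme-constrained models are built to
# capture.  Five sugars (glucose, cellobiose with hydrolytic and
# phosphorolytic cleavage routes, xylose, galactose via a Leloir-style
# entry, arabinose with two extra enzymatic steps) feed lumped glycolysis,
# a non-oxidative pentose-phosphate shunt, a TCA loop, oxidative
# phosphorylation (high ATP yield, high enzyme mass per flux) and ethanol
# fermentation (low ATP yield, cheap enzymes).  Enzyme-cost contrasts are
# encoded in the kcat/MW tables:
#   * respiration carries a 1000-kDa complex, so ATP made oxidatively is
#     enzyme-expensive -- growth saturates once the proteome pool binds and
#     surplus carbon overflows to ethanol;
#   * the phosphorolytic cellobiose route saves one ATP per two hexoses,
#     which beats glucose wherever ATP demand forces oxphos flux, while the
#     cheaper plain glucose entry wins for pyruvate (glycolysis is
#     ATP-positive there), giving the designed glucose/cellobiose
#     co-utilization;
#   * galactose (hexose entry, extra phosphoglucomutase step) and xylose
#     (pentose entry) each win on "their" side of the network, giving mixed
#     dominance; arabinose pays two extra enzymes and loses everywhere.

MINICORE_PRECURSORS <- c("g6p_c", "f6p_c", "g3p_c", "pg3_c", "pep_c", "pyr_c",
                         "accoa_c", "oaa_c", "akg_c", "succ_c", "e4p_c", "r5p_c")

#' Generate the minicore fixture
#'
#' Deterministic (no randomness): two calls return identical objects. The
#' returned configuration names the ATP metabolite, the oxidative-
#' phosphorylation and overflow reactions, the twelve biomass precursors,
#' the five substrates with carbon counts, and the designed ground truth
#' (hierarchy tiers and engineering-target directions) that the network was
#' built to exhibit.
#'
#' @return `list(model = MetabolicModel, kcat_table = , subunit_table = ,
#'   config = )`.
#' @export
make_minicore <- function() {
  M <- list(
    # id, compartment, carbon count, formula (externals only)
    c("glc_e",   "e", 6,  "C6H12O6"),
    c("cellb_e", "e", 12, "C12H22O11"),
    c("xyl_e",   "e", 5,  "C5H10O5"),
    c("gal_e",   "e", 6,  "C6H12O6"),
    c("ara_e",   "e", 5,  "C5H10O5"),
    c("o2_e",    "e", 0,  "O2"),
    c("etoh_e",  "e", 2,  "C2H6O"),
    c("co2_e",   "e", 1,  "CO2"),
    c("o2_c",    "c", 0,  NA),
    c("etoh_c",  "c", 2,  NA),
    c("co2_c",   "c", 1,  NA),
    c("acald_c", "c", 2,  NA),
    c("aral_c",  "c", 5,  NA),
    c("g1p_c",   "c", 6,  NA),
    c("g6p_c",   "c", 6,  NA),
    c("f6p_c",   "c", 6,  NA),
    c("g3p_c",   "c", 3,  NA),
    c("pg3_c",   "c", 3,  NA),
    c("pep_c",   "c", 3,  NA),
    c("pyr_c",   "c", 3,  NA),
    c("accoa_c", "c", 2,  NA),
    c("oaa_c",   "c", 4,  NA),
    c("akg_c",   "c", 5,  NA),
    c("succ_c",  "c", 4,  NA),
    c("e4p_c",   "c", 4,  NA),
    c("r5p_c",   "c", 5,  NA),
    c("atp_c",   "c", 0,  NA),
    c("adp_c",   "c", 0,  NA),
    c("nadh_c",  "c", 0,  NA),
    c("nad_c",   "c", 0,  NA))
  mets <- do.call(rbind, lapply(M, function(x)
    metabolite(id = x[1], compartment = x[2],
               carbon_count = as.integer(x[3]),
               formula = if (is.na(x[4])) NA_character_ else x[4])))

  rx <- function(id, st, lb = 0, ub = 1000, gpr = "", subsystem = NA) {
    reaction(id, st, lb, ub, gpr = gpr, subsystem = subsystem)
  }
  rxns <- list(
    # exchanges (uptake = negative flux)
    rx("EX_glc",   c(glc_e = -1),   -1000, 1000, subsystem = "exchange"),
    rx("EX_cellb", c(cellb_e = -1), -1000, 1000, subsystem = "exchange"),
    rx("EX_xyl",   c(xyl_e = -1),   -1000, 1000, subsystem = "exchange"),
    rx("EX_gal",   c(gal_e = -1),   -1000, 1000, subsystem = "exchange"),
    rx("EX_ara",   c(ara_e = -1),   -1000, 1000, subsystem = "exchange"),
    rx("EX_o2",    c(o2_e = -1),    -12, 0,      subsystem = "exchange"),
    rx("EX_etoh",  c(etoh_e = -1),  0, 1000,     subsystem = "exchange"),
    rx("EX_co2",   c(co2_e = -1),   0, 1000,     subsystem = "exchange"),
    # enzyme-free transport
    rx("O2t",   c(o2_e = -1, o2_c = 1),     0, 1000, subsystem = "transport"),
    rx("ETOHt", c(etoh_c = -1, etoh_e = 1), 0, 1000, subsystem = "transport"),
    rx("CO2t",  c(co2_c = -1, co2_e = 1),   0, 1000, subsystem = "transport"),
    # sugar entry
    rx("GLCup", c(glc_e = -1, atp_c = -1, g6p_c = 1, adp_c = 1),
       gpr = "hxt", subsystem = "uptake"),
    rx("GALup", c(gal_e = -1, atp_c = -1, g1p_c = 1, adp_c = 1),
       gpr = "gal1", subsystem = "uptake"),
    rx("CELBH", c(cellb_e = -1, atp_c = -2, g6p_c = 2, adp_c = 2),
       gpr = "bgl", subsystem = "uptake"),
    rx("CELBP", c(cellb_e = -1, atp_c = -1, g6p_c = 1, g1p_c = 1, adp_c = 1),
       gpr = "cbp", subsystem = "uptake"),
    rx("XYLup", c(xyl_e = -1, atp_c = -1, r5p_c = 1, adp_c = 1),
       gpr = "xyl1", subsystem = "uptake"),
    rx("ARA1", c(ara_e = -1, aral_c = 1), gpr = "ara1", subsystem = "uptake"),
    rx("ARA2", c(aral_c = -1, atp_c = -1, r5p_c = 1, adp_c = 1),
       gpr = "ara2", subsystem = "uptake"),
    rx("PGM", c(g1p_c = -1, g6p_c = 1), gpr = "pgm", subsystem = "uptake"),
    # glycolysis (lumped)
    rx("PGI", c(g6p_c = -1, f6p_c = 1), -1000, 1000, gpr = "pgi1 or pgi2",
       subsystem = "glycolysis"),
    rx("PFK", c(f6p_c = -1, atp_c = -1, g3p_c = 2, adp_c = 1),
       gpr = "pfk", subsystem = "glycolysis"),
    rx("GAPD", c(g3p_c = -1, adp_c = -1, nad_c = -1,
                 pg3_c = 1, atp_c = 1, nadh_c = 1),
       gpr = "gapdh", subsystem = "glycolysis"),
    rx("ENO", c(pg3_c = -1, pep_c = 1), -1000, 1000, gpr = "eno",
       subsystem = "glycolysis"),
    rx("PYK", c(pep_c = -1, adp_c = -1, pyr_c = 1, atp_c = 1),
       gpr = "pyk", subsystem = "glycolysis"),
    # non-oxidative pentose phosphate shunt (lumped, carbon-balanced)
    rx("TKT1", c(f6p_c = -1, g3p_c = -1, e4p_c = 1, r5p_c = 1), -1000, 1000,
       gpr = "tkt", subsystem = "ppp"),
    rx("TKT2", c(r5p_c = -2, f6p_c = 1, e4p_c = 1), -1000, 1000,
       gpr = "tal", subsystem = "ppp"),
    # TCA (lumped)
    rx("PDH", c(pyr_c = -1, nad_c = -1, accoa_c = 1, co2_c = 1, nadh_c = 1),
       gpr = "pdh", subsystem = "tca"),
    rx("PYC", c(pyr_c = -1, atp_c = -1, co2_c = -1, oaa_c = 1, adp_c = 1),
       gpr = "pyc", subsystem = "tca"),
    rx("CS", c(accoa_c = -1, oaa_c = -1, nad_c = -1,
               akg_c = 1, co2_c = 1, nadh_c = 1),
       gpr = "cit", subsystem = "tca"),
    rx("AKGD", c(akg_c = -1, nad_c = -1, adp_c = -0.5,
                 succ_c = 1, co2_c = 1, nadh_c = 1, atp_c = 0.5),
       gpr = "akgd", subsystem = "tca"),
    rx("SDH", c(succ_c = -1, nad_c = -2, oaa_c = 1, nadh_c = 2),
       gpr = "sdh", subsystem = "tca"),
    # oxidative phosphorylation (P/O = 2), one big complex
    rx("OXPHOS", c(nadh_c = -1, o2_c = -0.5, adp_c = -2,
                   nad_c = 1, atp_c = 2),
       gpr = "nd1 and nd2 and atps", subsystem = "oxphos"),
    # alternative oxidase: NADH reoxidation uncoupled from ATP synthesis
    rx("AOX", c(nadh_c = -1, o2_c = -0.5, nad_c = 1),
       gpr = "aox", subsystem = "oxphos"),
    # ethanol fermentation
    rx("PDC", c(pyr_c = -1, acald_c = 1, co2_c = 1),
       gpr = "pdc", subsystem = "fermentation"),
    rx("ADH", c(acald_c = -1, nadh_c = -1, etoh_c = 1, nad_c = 1),
       gpr = "adh", subsystem = "fermentation"),
    # non-enzymatic ATP dissipation (no forced maintenance)
    rx("ATPM", c(atp_c = -1, adp_c = 1), 0, 1000, subsystem = "maintenance"),
    # biomass from the 12 precursors plus ATP
    rx("BIOMASS", c(g6p_c = -1.2, f6p_c = -0.6, g3p_c = -0.6,
                    pg3_c = -1.2, pep_c = -1.2, pyr_c = -1.8,
                    accoa_c = -3.6, oaa_c = -1.8, akg_c = -1.2,
                    succ_c = -0.36, e4p_c = -0.36, r5p_c = -0.96,
                    atp_c = -24, adp_c = 24),
       0, 1000, subsystem = "biomass"))

  # gene molecular weights (kDa per subunit) and complex subunit counts
  subunits <- data.frame(
    gene_id = c("hxt", "gal1", "pgm", "bgl", "cbp", "xyl1", "ara1", "ara2",
                "pgi1", "pgi2", "pfk", "gapdh", "eno", "pyk", "tkt", "tal",
                "pdh", "pyc", "cit", "akgd", "sdh", "nd1", "nd2", "atps",
                "aox", "pdc", "adh"),
    subunit_mw_kda = c(100, 120, 40, 150, 120, 110, 100, 100,
                       55, 60, 85, 36, 47, 55, 68, 35,
                       160, 130, 100, 150, 120, 400, 350, 125,
                       30, 60, 40),
    subunit_count = c(1, 1, 1, 1, 1, 1, 1, 1,
                      1, 1, 1, 1, 1, 1, 1, 1,
                      1, 1, 1, 1, 1, 1, 1, 2,
                      1, 1, 1),
    stringsAsFactors = FALSE)

  # turnover numbers (1/s); keyed by pre-split reaction id except for the
  # slower second PGI isozyme, keyed by its post-split copy id
  kcat <- data.frame(
    reaction_id = c("GLCup", "GALup", "CELBH", "CELBP", "XYLup", "ARA1",
                    "ARA2", "PGM", "PGI", "PGI_num2", "PFK", "GAPD", "ENO",
                    "PYK", "TKT1", "TKT2", "PDH", "PYC", "CS", "AKGD",
                    "SDH", "OXPHOS", "AOX", "PDC", "ADH"),
    kcat_s = c(20, 11, 8, 10, 5.8, 2.0,
               2.0, 60, 40, 30, 30, 40, 36,
               40, 1.3, 0.65, 20, 16, 20, 18,
               20, 7.2, 40, 30, 36),
    source = c("database", "turnup_predicted", "database", "turnup_predicted",
               "turnup_predicted", "dl_predicted", "dl_predicted", "database",
               "database", "turnup_predicted", "database", "database",
               "database", "database", "turnup_predicted", "turnup_predicted",
               "database", "turnup_predicted", "database", "turnup_predicted",
               "turnup_predicted", "database", "database", "database",
               "database"),
    stringsAsFactors = FALSE)

  genes <- data.frame(id = subunits$gene_id,
                      protein = paste0("P_", toupper(subunits$gene_id)),
                      mw_kda = subunits$subunit_mw_kda,
                      stringsAsFactors = FALSE)
  model <- metabolic_model(mets, rxns, genes = genes, objective = "BIOMASS")

  substrates <- data.frame(
    substrate = c("glucose", "cellobiose", "xylose", "galactose", "arabinose"),
    exchange_id = c("EX_glc", "EX_cellb", "EX_xyl", "EX_gal", "EX_ara"),
    carbon_count = c(6L, 12L, 5L, 6L, 5L),
    mw_g_mmol = c(0.18016, 0.34230, 0.15013, 0.18016, 0.15013),
    stringsAsFactors = FALSE)

  config <- list(
    biomass_id = "BIOMASS",
    atp_metabolite_id = "atp_c",
    oxphos_reaction_ids = "OXPHOS",
    overflow_exchange_ids = "EX_etoh",
    o2_exchange_id = "EX_o2",
    precursor_ids = MINICORE_PRECURSORS,
    substrates = substrates,
    ptot = 0.4653,
    f = 0.55,
    sigma = 0.5,
    # 13C MFA resolves central carbon fluxes only; cofactor turnover and
    # oxidative phosphorylation are not directly observable
    c13_reaction_ids = c("GLCup", "PGI", "PFK", "GAPD", "PYK", "PDH", "CS",
                         "AKGD", "SDH"),
    # 13C measurements emulate a carbon-limited culture (below the uptake
    # where the enzyme pool saturates), the regime where fluxes are
    # stoichiometry-determined and flux ratios are experimentally resolvable
    c13_glc_uptake = 2.4,
    designed_tiers = list(c("cellobiose", "glucose"),
                          c("galactose", "xylose"),
                          "arabinose"),
    designed_targets = list(
      product = "EX_etoh",
      top_cost_genes = c("pdc", "adh"),
      enhance_reactions = c("PDC", "ADH"),
      weaken_reactions = "OXPHOS"))

  list(model = model, kcat_table = kcat, subunit_table = subunits,
       config = config)
}

#' Build the enzyme-constrained minicore
#'
#' Splits the minicore, attaches its enzyme tables and pool bound.
#'
#' @param ptot,f,sigma pool parameters (defaults: total protein fraction
#'   0.4653, enzyme mass fraction 0.55, saturation 0.5).
#' @return `list(ec = ECModel, split_map = , base = unsplit model,
#'   config = )`.
#' @export
make_minicore_ec <- function(ptot = 0.4653, f = 0.55, sigma = 0.5) {
  mc <- make_minicore()
  sp <- split_model(mc$model)
  entries <- make_enzyme_entries(sp$model, mc$kcat_table, mc$subunit_table,
                                 sigma = sigma)
  ec <- build_ec_model(sp$model, entries, ptot = ptot, f = f,
                       split_map = sp$split_map)
  list(ec = ec, split_map = sp$split_map, base = mc$model,
       config = mc$config, kcat_table = mc$kcat_table,
       subunit_table = mc$subunit_table)
}
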