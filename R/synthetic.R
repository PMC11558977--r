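# Random synthetic inputs: toy models, proteomes with a planted enzyme mass
# fraction, kcat perturbations and noisy flux measurement tables.  Every
# generator takes an explicit seed and restores the caller's RNG state.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a random feasible toy model
#'
#' One substrate exchange, a linear backbone threading every metabolite (so
#' the model is connected and carries a positive optimum), plus random extra
#' interior reactions.
#'
#' @param n_metabolites,n_reactions sizes; `n_reactions >= n_metabolites >= 3`
#'   (the backbone uses `n_metabolites + 2` of the reaction budget:
#'   substrate exchange, chain, biomass drain).
#' @param seed integer seed; identical seeds give identical models.
#' @return a `MetabolicModel`.
#' @export
make_random_toy <- function(n_metabolites, n_reactions, seed) {
  if (n_metabolites < 3 || n_reactions < n_metabolites)
    stop("need n_reactions >= n_metabolites >= 3", call. = FALSE)
  with_seed(seed, {
    mids <- sprintf("m%02d_c", seq_len(n_metabolites))
    mets <- do.call(rbind, lapply(mids, function(m) metabolite(m)))
    rxns <- list(reaction("EX_sub", stats::setNames(-1, mids[1]), -10, 1000))
    for (i in seq_len(n_metabolites - 1L)) {
      rxns[[length(rxns) + 1L]] <-
        reaction(sprintf("CHAIN%02d", i),
                 stats::setNames(c(-1, 1), mids[c(i, i + 1L)]),
                 0, 1000, gpr = sprintf("g%02d", i))
    }
    rxns[[length(rxns) + 1L]] <-
      reaction("BIOMASS", stats::setNames(-1, mids[n_metabolites]), 0, 1000)
    n_extra <- n_reactions - length(rxns)
    k <- 0L
    while (k < n_extra) {
      pair <- sample(n_metabolites, 2)
      k <- k + 1L
      coef <- round(stats::runif(1, 0.5, 2), 2)
      rxns[[length(rxns) + 1L]] <-
        reaction(sprintf("RND%02d", k),
                 stats::setNames(c(-1, coef), mids[pair]),
                 0, round(stats::runif(1, 1, 100), 1),
                 gpr = sprintf("gr%02d", k))
    }
    metabolic_model(mets, rxns, objective = "BIOMASS")
  })
}

#' Synthesize a proteome with a planted enzyme mass fraction
#'
#' Model proteins receive random abundances; `n_extra_proteins` background
#' proteins are scaled so that [enzyme_mass_fraction()] recovers `planted_f`
#' exactly.
#'
#' @param model a `MetabolicModel` (its genes' `protein` accessions and
#'   `mw_kda` are used; missing MWs default to 50 kDa).
#' @param planted_f target enzyme mass fraction in (0, 1].
#' @param n_extra_proteins background (non-model) proteins.
#' @param seed integer seed.
#' @return `list(proteome = data.frame, ground_truth = list(planted_f, ...))`.
#' @export
synth_proteome <- function(model, planted_f = 0.55, n_extra_proteins = 50L,
                           seed = 1L) {
  if (planted_f <= 0 || planted_f > 1)
    stop("planted_f must be in (0, 1]", call. = FALSE)
  if (planted_f == 1 && n_extra_proteins > 0)
    stop("planted_f = 1 is inconsistent with background proteins", call. = FALSE)
  genes <- model$genes
  prot <- ifelse(is.na(genes$protein), paste0("P_", genes$id), genes$protein)
  mw <- ifelse(is.na(genes$mw_kda), 50, genes$mw_kda)
  with_seed(seed, {
    ab_model <- stats::runif(length(prot), 0.1, 10)
    model_mass <- sum(ab_model * mw)
    if (n_extra_proteins > 0) {
      mw_bg <- stats::runif(n_extra_proteins, 10, 200)
      ab_bg <- stats::runif(n_extra_proteins, 0.1, 10)
      # scale background so model mass is exactly planted_f of the total
      target_bg_mass <- model_mass * (1 - planted_f) / planted_f
      ab_bg <- ab_bg * target_bg_mass / sum(ab_bg * mw_bg)
      proteome <- data.frame(
        protein_id = c(prot, sprintf("BG_%03d", seq_len(n_extra_proteins))),
        abundance_mole_ratio = c(ab_model, ab_bg),
        mw_kda = c(mw, mw_bg), stringsAsFactors = FALSE)
    } else {
      proteome <- data.frame(protein_id = prot,
                             abundance_mole_ratio = ab_model,
                             mw_kda = mw, stringsAsFactors = FALSE)
    }
    list(proteome = proteome,
         ground_truth = list(planted_f = planted_f,
                             model_protein_ids = prot, seed = seed))
  })
}

#' Perturb the kcats of an ECModel
#'
#' @param ec an `ECModel`.
#' @param factor multiplier (> 0), applied to `subset` (default all entries).
#' @param subset reaction ids to perturb.
#' @param seed unused unless `factor` is given as a range `c(lo, hi)`, in
#'   which case per-reaction factors are drawn uniformly.
#' @return `list(model = perturbed ECModel, ground_truth = list(
#'   original_kcats = named vector, factor = , subset = ))`.
#' @export
perturb_kcats <- function(ec, factor, subset = NULL, seed = 1L) {
  stopifnot(all(factor > 0))
  if (is.null(subset)) subset <- names(ec$enzymes)
  bad <- setdiff(subset, names(ec$enzymes))
  if (length(bad))
    stop("no enzyme entry for: ", paste(bad, collapse = ", "), call. = FALSE)
  original <- vapply(ec$enzymes[subset], `[[`, numeric(1), "kcat")
  facs <- if (length(factor) == 2L) {
    with_seed(seed, stats::runif(length(subset), factor[1], factor[2]))
  } else rep_len(factor, length(subset))
  for (i in seq_along(subset)) {
    ec$enzymes[[subset[i]]]$kcat <- ec$enzymes[[subset[i]]]$kcat * facs[i]
  }
  list(model = ec,
       ground_truth = list(original_kcats = original, factor = factor,
                           subset = subset, seed = seed))
}

#' Synthesize a 13C-style flux measurement table
#'
#' pFBA net fluxes of designated central reactions under the given
#' conditions, multiplied by lognormal noise with coefficient of variation
#' `noise_cv`; per-measurement relative tolerances are
#' `max(2 * noise_cv, 0.05)`.
#'
#' @param ec an `ECModel`.
#' @param split_map its `SplitMap`.
#' @param reaction_ids original-model reactions to "measure".
#' @param conditions named uptake bounds, exchange id -> rate.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed integer seed.
#' @return data.frame with columns `reaction_id`, `flux_mmol_gdw_h`,
#'   `rel_tolerance`.
#' @export
synth_c13_fluxes <- function(ec, split_map, reaction_ids, conditions = list(),
                             noise_cv = 0, seed = 1L) {
  stopifnot(noise_cv >= 0)
  ec <- apply_conditions(ec, conditions)
  sol <- pfba(ec)
  if (sol$status != "optimal")
    stop("model infeasible under the given conditions", call. = FALSE)
  net <- net_fluxes(sol$fluxes, split_map)
  bad <- setdiff(reaction_ids, names(net))
  if (length(bad))
    stop("unknown reaction id(s): ", paste(bad, collapse = ", "), call. = FALSE)
  flux <- net[reaction_ids]
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    noise <- with_seed(seed,
                       stats::rlnorm(length(flux), meanlog = -sdlog^2 / 2,
                                     sdlog = sdlog))
    flux <- flux * noise
  }
  data.frame(reaction_id = reaction_ids,
             flux_mmol_gdw_h = unname(flux),
             rel_tolerance = max(2 * noise_cv, 0.05),
             stringsAsFactors = FALSE)
}
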