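# Headline analyses: the metabolic-adjustment scan (yield, enzyme efficiency,
# energy cost, oxidative-phosphorylation share, stage labels), carbon-source
# hierarchy from precursor enzyme efficiencies, and the two enzyme-cost-based
# target prediction methods.

STAGE_LEVELS <- c("substrate_limited", "metabolic_adjustment", "metabolic_overflow")

#' Metabolic-adjustment scan over substrate uptake rates
#'
#' For each uptake rate the substrate uptake is fixed at that rate, growth is
#' maximized by pFBA and the solution summarized:
#' biomass yield `v_bio / (v_substrate * MW_substrate)` (gDW per g substrate),
#' enzyme efficiency for biomass `epsilon = v_bio / E_min` with `E_min` the
#' minimum total enzyme supporting that biomass flux, the energy-synthesis
#' enzyme cost `sum_i E_i / v_ATP,i` over ATP-producing reactions, the share
#' of ATP made by the designated oxidative-phosphorylation reactions, the
#' overflow secretion flux, and a stage label: `substrate_limited` while the
#' enzyme pool has slack, `metabolic_overflow` once overflow secretion is
#' active, `metabolic_adjustment` in between.
#'
#' @param ec an `ECModel`.
#' @param substrate_exchange_id substrate exchange reaction (original id).
#' @param uptake_rates ascending non-negative uptake rates, mmol/gDW/h.
#' @param substrate_mw substrate molecular weight in g/mmol (e.g. 0.18016
#'   for glucose).
#' @param atp_metabolite_id id of the ATP metabolite.
#' @param oxphos_reaction_ids reactions counted as oxidative phosphorylation.
#' @param overflow_exchange_ids overflow (fermentation-product) exchanges.
#' @param pool_tol slack threshold for the stage call.
#' @return data.frame with one row per uptake rate.
#' @export
adjustment_scan <- function(ec, substrate_exchange_id, uptake_rates,
                            substrate_mw, atp_metabolite_id,
                            oxphos_reaction_ids, overflow_exchange_ids,
                            pool_tol = 1e-6) {
  stopifnot(inherits(ec, "ECModel"))
  if (is.unsorted(uptake_rates) || any(uptake_rates < 0))
    stop("uptake_rates must be non-negative and ascending", call. = FALSE)
  S <- stoich_matrix(ec)
  if (!atp_metabolite_id %in% rownames(S))
    stop("unknown ATP metabolite: ", atp_metabolite_id, call. = FALSE)
  atp_row <- S[atp_metabolite_id, ]

  flux_of <- function(sol, ids) {
    ids <- ids[ids %in% names(sol$fluxes)]
    sum(sol$fluxes[ids])
  }
  overflow_split <- unlist(lapply(overflow_exchange_ids, function(ex) {
    ids <- rxn_ids(ec)
    c(ex, paste0(ex, "_reverse"))[c(ex, paste0(ex, "_reverse")) %in% ids][1]
  }))

  rows <- lapply(uptake_rates, function(u) {
    m <- set_uptake(ec, substrate_exchange_id, u)
    # the scan forces the cell to take up the substrate at exactly this rate
    rev_id <- paste0(substrate_exchange_id, "_reverse")
    if (rev_id %in% rxn_ids(m)) m <- set_bounds(m, rev_id, lb = u, ub = u)
    sol <- pfba(m)
    if (sol$status != "optimal") {
      return(data.frame(uptake = u, growth = NA_real_, biomass_yield = NA_real_,
                        epsilon_biomass = NA_real_, energy_cost = NA_real_,
                        oxphos_ratio = NA_real_, overflow_flux = NA_real_,
                        stage = NA_character_, flag = "infeasible",
                        stringsAsFactors = FALSE))
    }
    growth <- sol$objective_value
    flag <- NA_character_
    if (u <= 0) {
      yield <- 0
      flag <- "zero_uptake"
    } else {
      yield <- growth / (u * substrate_mw)
    }
    # minimum enzyme supporting this biomass flux, substrate available at <= u
    m_free <- set_uptake(ec, substrate_exchange_id, u)
    biomass_id <- ec$base$objective
    emin_sol <- min_enzyme_solution(m_free, stats::setNames(growth, biomass_id))
    e_min <- if (emin_sol$status == "optimal") emin_sol$objective_value else NA_real_
    eps_biomass <- if (!is.na(e_min) && e_min > 0) growth / e_min else 0

    # ATP production per reaction in the carried (non-negative) direction
    v <- pmax(sol$fluxes, 0)
    atp_prod <- atp_row * v[names(atp_row)]
    producers <- names(atp_prod)[atp_prod > 1e-9]
    usage <- sol$enzyme_usage
    energy_cost <- sum(vapply(producers, function(r) {
      e <- if (r %in% names(usage)) usage[[r]] else 0
      e / atp_prod[[r]]
    }, numeric(1)))
    total_atp <- sum(atp_prod[producers])
    oxp_ids <- unlist(lapply(oxphos_reaction_ids, function(id) {
      s <- c(id, paste0(id, "_num", 1:8))
      s[s %in% names(atp_prod)]
    }))
    oxp_atp <- sum(atp_prod[intersect(oxp_ids, producers)])
    oxphos_ratio <- if (total_atp > 1e-9) oxp_atp / total_atp else NA_real_

    over <- flux_of(sol, overflow_split)
    slack <- ec$pool_bound - sum(usage)
    stage <- if (over > pool_tol) "metabolic_overflow"
             else if (slack > pool_tol) "substrate_limited"
             else "metabolic_adjustment"
    data.frame(uptake = u, growth = growth, biomass_yield = yield,
               epsilon_biomass = eps_biomass, energy_cost = energy_cost,
               oxphos_ratio = oxphos_ratio, overflow_flux = over,
               stage = stage, flag = flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Enzyme efficiency for biomass precursor synthesis
#'
#' With the substrate's uptake bounded at `carbon_uptake / carbon_count`
#' (equal carbon supply across substrates), each precursor in turn receives a
#' temporary enzyme-free unit drain; the drain flux is maximized, the minimum
#' total enzyme at that flux is computed, and the efficiency is
#' `epsilon = v / E_min`.
#'
#' @param ec an `ECModel`.
#' @param substrate_exchange_id the substrate's exchange reaction.
#' @param carbon_count carbon atoms per substrate molecule.
#' @param precursor_ids metabolite ids of the biomass precursors.
#' @param carbon_uptake substrate carbon uptake, mmol C/gDW/h.
#' @param closed_exchange_ids exchanges whose uptake is shut off first
#'   (competing substrates).
#' @return data.frame with columns `precursor`, `flux`, `e_min`, `epsilon`,
#'   `flag`.
#' @export
precursor_efficiency <- function(ec, substrate_exchange_id, carbon_count,
                                 precursor_ids, carbon_uptake = 15,
                                 closed_exchange_ids = NULL) {
  stopifnot(inherits(ec, "ECModel"), carbon_count > 0)
  for (ex in setdiff(closed_exchange_ids, substrate_exchange_id))
    ec <- set_uptake(ec, ex, 0)
  ec <- set_uptake(ec, substrate_exchange_id, carbon_uptake / carbon_count)
  bad <- setdiff(precursor_ids, met_ids(ec))
  if (length(bad))
    stop("unknown precursor metabolite(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  rows <- lapply(precursor_ids, function(p) {
    drain_id <- paste0("DRAIN_", p)
    m <- ec
    m$base$reactions[[drain_id]] <-
      reaction(drain_id, stats::setNames(-1, p), 0, 1000,
               name = paste("drain of", p))
    sol <- fba(m, objective_id = drain_id, direction = "max")
    v <- if (sol$status == "optimal") sol$objective_value else 0
    if (v <= 1e-9) {
      return(data.frame(precursor = p, flux = 0, e_min = NA_real_,
                        epsilon = 0, flag = "unreachable",
                        stringsAsFactors = FALSE))
    }
    emin <- min_enzyme_solution(m, stats::setNames(v, drain_id))
    e_min <- emin$objective_value
    data.frame(precursor = p, flux = v, e_min = e_min,
               epsilon = if (e_min > 0) v / e_min else Inf,
               flag = NA_character_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Precursor-efficiency matrix over several substrates
#'
#' Convenience wrapper running [precursor_efficiency()] for each substrate
#' with all competing substrate uptakes closed.
#'
#' @param ec an `ECModel`.
#' @param substrates data.frame with columns `substrate`, `exchange_id`,
#'   `carbon_count`.
#' @param precursor_ids metabolite ids of the biomass precursors.
#' @param carbon_uptake substrate carbon uptake, mmol C/gDW/h.
#' @return numeric matrix substrates x precursors of efficiencies.
#' @export
efficiency_matrix <- function(ec, substrates, precursor_ids,
                              carbon_uptake = 15) {
  eff <- matrix(NA_real_, nrow(substrates), length(precursor_ids),
                dimnames = list(substrates$substrate, precursor_ids))
  for (i in seq_len(nrow(substrates))) {
    res <- precursor_efficiency(
      ec, substrates$exchange_id[i], substrates$carbon_count[i],
      precursor_ids, carbon_uptake = carbon_uptake,
      closed_exchange_ids = substrates$exchange_id)
    eff[i, ] <- res$epsilon
  }
  eff
}

#' Substrate hierarchy from a precursor-efficiency matrix
#'
#' Substrate a is preferred over b iff its efficiency is strictly higher for
#' every precursor; mixed (or tied) comparisons mean co-utilization. Tiers
#' are built by repeatedly extracting the substrates not strictly dominated
#' by any remaining substrate.
#'
#' @param efficiency matrix substrates x precursors (rownames = substrates).
#' @return an object of class `HierarchyResult`: list with `efficiency`,
#'   `dominance` (data.frame `first`, `second`, `verdict`) and `tiers`
#'   (list of character vectors, most preferred first).
#' @export
hierarchy_order <- function(efficiency) {
  if (any(efficiency < 0, na.rm = TRUE))
    stop("efficiencies must be non-negative", call. = FALSE)
  subs <- rownames(efficiency)
  dominates <- function(a, b) all(efficiency[a, ] > efficiency[b, ])
  pairs <- utils::combn(subs, 2, simplify = FALSE)
  dominance <- do.call(rbind, lapply(pairs, function(p) {
    v <- if (dominates(p[1], p[2])) "first_preferred"
         else if (dominates(p[2], p[1])) "second_preferred"
         else "co_utilized"
    data.frame(first = p[1], second = p[2], verdict = v,
               stringsAsFactors = FALSE)
  }))
  remaining <- subs
  tiers <- list()
  while (length(remaining)) {
    top <- Filter(function(b) {
      !any(vapply(setdiff(remaining, b), function(a) dominates(a, b), logical(1)))
    }, remaining)
    if (!length(top)) top <- remaining  # cyclic dominance cannot occur with
                                        # strict 'all' comparisons, but guard
    tiers[[length(tiers) + 1L]] <- sort(top)
    remaining <- setdiff(remaining, top)
  }
  structure(list(efficiency = efficiency, dominance = dominance,
                 tiers = tiers),
            class = "HierarchyResult")
}

#' @export
print.HierarchyResult <- function(x, ...) {
  cat("HierarchyResult:", nrow(x$efficiency), "substrates,",
      ncol(x$efficiency), "precursors\n")
  for (i in seq_along(x$tiers))
    cat(sprintf("  tier %d: %s\n", i, paste(x$tiers[[i]], collapse = ", ")))
  invisible(x)
}

# internal: per-gene enzyme cost of a solution, complexes split by mass share
gene_costs <- function(ec, usage) {
  costs <- numeric(0)
  for (e in ec$enzymes) {
    u <- if (e$reaction_id %in% names(usage)) usage[[e$reaction_id]] else 0
    if (u <= 0) next
    share <- (e$complex$subunit_count * e$complex$subunit_mw) / e$assembled_mw
    for (k in seq_len(nrow(e$complex))) {
      g <- e$complex$gene_id[k]
      costs[g] <- (if (g %in% names(costs)) costs[[g]] else 0) + u * share[k]
    }
  }
  costs
}

#' Top enzyme-cost engineering targets (method 1)
#'
#' Maximizes the product by pFBA under the given conditions and ranks genes
#' by their total enzyme cost (complex usage split among member genes by
#' subunit mass share). The top `n` genes are candidate overexpression
#' (enhance) targets.
#'
#' @param ec an `ECModel`.
#' @param product_exchange_id the product's exchange reaction (original id).
#' @param conditions named uptake bounds, exchange id -> rate.
#' @param n number of top-demanded proteins to report.
#' @return a `TargetReport`: data.frame `identifier`, `score` (g enzyme/gDW),
#'   `direction`, `rank`; attributes `product`, `method`, `flag`.
#' @export
targets_top_cost <- function(ec, product_exchange_id, conditions = list(),
                             n = 15L) {
  ec2 <- apply_conditions(ec, conditions)
  prod_id <- product_rxn_id(ec2, product_exchange_id)
  sol <- pfba(ec2, objective_id = prod_id)
  flag <- NA_character_
  if (sol$status != "optimal" || sol$objective_value <= 1e-9) {
    out <- data.frame(identifier = character(0), score = numeric(0),
                      direction = character(0), rank = integer(0),
                      stringsAsFactors = FALSE)
    attr(out, "flag") <- "zero_product_optimum"
  } else {
    costs <- gene_costs(ec2, sol$enzyme_usage)
    costs <- costs[costs > 1e-12]
    ord <- order(-costs, names(costs))
    take <- utils::head(ord, n)
    out <- data.frame(identifier = names(costs)[take],
                      score = unname(costs[take]),
                      direction = "enhance",
                      rank = seq_along(take), stringsAsFactors = FALSE)
    attr(out, "flag") <- flag
  }
  attr(out, "product") <- product_exchange_id
  attr(out, "method") <- "top_cost"
  class(out) <- c("TargetReport", "data.frame")
  out
}

# internal: split id carrying product secretion
product_rxn_id <- function(ec, exchange_id) {
  ids <- rxn_ids(ec)
  if (exchange_id %in% ids) return(exchange_id)
  stop("unknown product exchange: ", exchange_id, call. = FALSE)
}

#' HGLP/LGHP engineering targets (method 2)
#'
#' Compares two states: HGLP (high growth, low product; biomass fixed at
#' 100% of its maximum, product maximized as secondary objective) and LGHP
#' (low growth, high product; biomass fixed at `low_biomass_fraction` of the
#' maximum). Reactions with flux above `flux_threshold` in either state are
#' candidates; a reaction whose enzyme cost (or, for enzyme-free reactions,
#' flux) is higher in LGHP is an enhance target, lower a weaken target.
#' Scores are LGHP - HGLP enzyme-cost differences.
#'
#' @param ec an `ECModel`.
#' @param product_exchange_id the product's exchange reaction.
#' @param conditions named uptake bounds, exchange id -> rate.
#' @param flux_threshold candidate flux cutoff, mmol/gDW/h.
#' @param low_biomass_fraction biomass fraction defining the LGHP state.
#' @return a `TargetReport` data.frame with one row per candidate reaction.
#' @export
targets_hglp_lghp <- function(ec, product_exchange_id, conditions = list(),
                              flux_threshold = 1, low_biomass_fraction = 0.1) {
  ec2 <- apply_conditions(ec, conditions)
  prod_id <- product_rxn_id(ec2, product_exchange_id)
  biomass_id <- ec2$base$objective
  mu <- fba(ec2, biomass_id, "max")
  if (mu$status != "optimal")
    stop("biomass optimization failed: ", mu$status, call. = FALSE)
  state <- function(frac) {
    m <- set_bounds(ec2, biomass_id, lb = frac * mu$objective_value * (1 - 1e-9),
                    ub = frac * mu$objective_value + 1e-12)
    sol <- pfba(m, objective_id = prod_id)
    if (sol$status != "optimal")
      stop("product optimization infeasible at biomass fraction ", frac,
           call. = FALSE)
    sol
  }
  hglp <- state(1)
  lghp <- state(low_biomass_fraction)
  rxns <- rxn_ids(ec2)
  vh <- hglp$fluxes[rxns]; vl <- lghp$fluxes[rxns]
  eh <- hglp$enzyme_usage[rxns]; el <- lghp$enzyme_usage[rxns]
  eh[is.na(eh)] <- 0; el[is.na(el)] <- 0
  cand <- rxns[pmax(vh, vl) > flux_threshold]
  tol <- 1e-9
  rows <- lapply(cand, function(r) {
    dcost <- el[[r]] - eh[[r]]
    dflux <- vl[[r]] - vh[[r]]
    direction <- if (dcost > tol || (abs(dcost) <= tol && dflux > tol)) "enhance"
                 else if (dcost < -tol || (abs(dcost) <= tol && dflux < -tol)) "weaken"
                 else "none"
    score <- if (abs(dcost) > tol) dcost else dflux
    data.frame(identifier = r, score = score, direction = direction,
               flux_hglp = vh[[r]], flux_lghp = vl[[r]],
               cost_hglp = eh[[r]], cost_lghp = el[[r]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(identifier = character(0), score = numeric(0),
                      direction = character(0), flux_hglp = numeric(0),
                      flux_lghp = numeric(0), cost_hglp = numeric(0),
                      cost_lghp = numeric(0), stringsAsFactors = FALSE)
  out <- out[order(-abs(out$score)), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "product") <- product_exchange_id
  attr(out, "method") <- "hglp_lghp"
  class(out) <- c("TargetReport", "data.frame")
  out
}

#' Read a flat key-value configuration file
#'
#' Lines of the form `key = value`; comma-separated values become vectors,
#' numeric-looking values are converted.
#'
#' @param path file path.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) next
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    nums <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(nums)) nums else parts
  }
  out
}
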