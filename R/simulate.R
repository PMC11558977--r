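# LP-based analyses: FBA, parsimonious FBA, minimum-enzyme solutions, flux
# variability analysis with isozyme/reversibility-aware aggregation, and
# phenotype phase planes.

# internal: model or ECModel -> LP pieces
as_lp <- function(model) {
  ec <- inherits(model, "ECModel")
  base <- if (ec) model$base else model
  S <- stoich_matrix(base)
  bnds <- model_bounds(base)
  pool <- if (ec) pool_coefficients(model) else NULL
  list(S = S, lb = bnds[, "lb"], ub = bnds[, "ub"], pool = pool,
       pool_bound = if (ec) model$pool_bound else NULL,
       rxns = colnames(S), ec = ec)
}

# internal: wrap an LP result as a FluxSolution
as_flux_solution <- function(model, status, objective, x, rxns) {
  fluxes <- if (is.null(x) || anyNA(x)) stats::setNames(rep(NA_real_, length(rxns)), rxns)
            else stats::setNames(x, rxns)
  usage <- NULL
  pool_util <- NA_real_
  if (inherits(model, "ECModel") && status == "optimal") {
    u <- enzyme_usage(model, pmax(fluxes, 0))
    usage <- u$usage
    pool_util <- u$total / model$pool_bound
  }
  structure(list(status = status, objective_value = objective, fluxes = fluxes,
                 enzyme_usage = usage, pool_utilization = pool_util),
            class = "FluxSolution")
}

#' @export
print.FluxSolution <- function(x, ...) {
  cat("FluxSolution:", x$status)
  if (x$status == "optimal") {
    cat(sprintf(", objective %.6g", x$objective_value))
    if (!is.na(x$pool_utilization))
      cat(sprintf(", pool utilization %.1f%%", 100 * x$pool_utilization))
  }
  cat("\n")
  invisible(x)
}

#' Flux balance analysis
#'
#' Maximizes (or minimizes) the flux of one reaction subject to steady state
#' `S v = 0`, flux bounds, and -- for an `ECModel` -- the enzyme pool row.
#'
#' @param model a `MetabolicModel` or `ECModel`.
#' @param objective_id reaction whose flux is optimized; defaults to the
#'   model's declared objective.
#' @param direction `"max"` or `"min"`.
#' @return a `FluxSolution`. Infeasibility/unboundedness is reported in
#'   `$status`, not raised.
#' @export
fba <- function(model, objective_id = NULL, direction = c("max", "min")) {
  direction <- match.arg(direction)
  lp <- as_lp(model)
  if (is.null(objective_id))
    objective_id <- if (inherits(model, "ECModel")) model$base$objective else model$objective
  if (!objective_id %in% lp$rxns)
    stop("unknown objective reaction: ", objective_id, call. = FALSE)
  obj <- as.numeric(lp$rxns == objective_id)
  res <- solve_lp(obj,
                  Aeq = lp$S, beq = rep(0, nrow(lp$S)),
                  Ale = if (lp$ec) matrix(lp$pool, 1) else NULL,
                  ble = lp$pool_bound,
                  lb = lp$lb, ub = lp$ub,
                  maximize = direction == "max")
  status <- res$status
  if (status == "optimal" && abs(res$objective) >= 9.9e6) status <- "unbounded"
  as_flux_solution(model, status, res$objective, res$x, lp$rxns)
}

#' Parsimonious FBA
#'
#' Two-stage lexicographic LP: fix the objective flux at its FBA optimum,
#' then minimize the total absolute flux. Models with reversible reactions
#' are split internally so the second stage is a plain sum; fluxes are
#' reported on the model's own reaction ids (net fluxes for reversible
#' input).
#'
#' @param model a `MetabolicModel` or `ECModel`.
#' @param objective_id optimized reaction; default the model objective.
#' @return a `FluxSolution` whose `objective_value` equals the FBA optimum.
#' @export
pfba <- function(model, objective_id = NULL) {
  base <- if (inherits(model, "ECModel")) model$base else model
  if (is.null(objective_id)) objective_id <- base$objective
  if (any(model_bounds(base)[, "lb"] < 0)) {
    # reversible input: split, solve, report net fluxes
    if (inherits(model, "ECModel"))
      stop("an ECModel must be built on a split model", call. = FALSE)
    sp <- to_irreversible(model)
    sol <- pfba(sp$model, objective_id = objective_id)
    if (sol$status != "optimal") return(sol)
    net <- net_fluxes(sol$fluxes, sp$split_map)
    return(as_flux_solution(model, sol$status, sol$objective_value,
                            net[rxn_ids(model)], rxn_ids(model)))
  }
  first <- fba(model, objective_id, "max")
  if (first$status != "optimal") return(first)
  opt <- first$objective_value
  lp <- as_lp(model)
  lb <- lp$lb; ub <- lp$ub
  j <- match(objective_id, lp$rxns)
  lb[j] <- opt; ub[j] <- max(ub[j], opt)
  res <- solve_lp(rep(1, length(lp$rxns)),
                  Aeq = lp$S, beq = rep(0, nrow(lp$S)),
                  Ale = if (lp$ec) matrix(lp$pool, 1) else NULL,
                  ble = lp$pool_bound,
                  lb = lb, ub = ub, maximize = FALSE)
  if (res$status != "optimal") {
    # tiny numerical slack on the fixed optimum
    lb[j] <- opt * (1 - 1e-9) - 1e-12
    res <- solve_lp(rep(1, length(lp$rxns)), Aeq = lp$S, beq = rep(0, nrow(lp$S)),
                    Ale = if (lp$ec) matrix(lp$pool, 1) else NULL,
                    ble = lp$pool_bound, lb = lb, ub = ub, maximize = FALSE)
  }
  as_flux_solution(model, res$status, opt, res$x, lp$rxns)
}

#' Minimum-enzyme solution at fixed fluxes
#'
#' Minimizes the total enzyme usage `sum_i E_i` subject to steady state, the
#' pool row, bounds, and user-fixed fluxes (typically the biomass or a
#' precursor drain flux).
#'
#' @param ec an `ECModel`.
#' @param fixed named numeric vector of fluxes to fix (lb = ub = value).
#' @return a `FluxSolution`; `objective_value` is the minimum total enzyme
#'   `E_min` in g/gDW.
#' @export
min_enzyme_solution <- function(ec, fixed = NULL) {
  stopifnot(inherits(ec, "ECModel"))
  lp <- as_lp(ec)
  lb <- lp$lb; ub <- lp$ub
  if (length(fixed)) {
    bad <- setdiff(names(fixed), lp$rxns)
    if (length(bad))
      stop("cannot fix unknown reaction(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    j <- match(names(fixed), lp$rxns)
    lb[j] <- fixed; ub[j] <- fixed
  }
  res <- solve_lp(lp$pool,
                  Aeq = lp$S, beq = rep(0, nrow(lp$S)),
                  Ale = matrix(lp$pool, 1), ble = lp$pool_bound,
                  lb = lb, ub = ub, maximize = FALSE)
  as_flux_solution(ec, res$status, res$objective, res$x, lp$rxns)
}

#' Raw per-reaction flux variability
#'
#' For each requested reaction, the minimum and maximum flux subject to the
#' objective being at least `fraction_of_optimum` times its FBA optimum
#' (two LPs per reaction).
#'
#' @param model a `MetabolicModel` or `ECModel`.
#' @param reaction_ids reactions to scan; default all.
#' @param fraction_of_optimum fraction of the FBA optimum to hold.
#' @return data.frame with columns `reaction_id`, `v_min`, `v_max`.
#' @export
fva_raw <- function(model, reaction_ids = NULL, fraction_of_optimum = 1.0) {
  lp <- as_lp(model)
  if (is.null(reaction_ids)) reaction_ids <- lp$rxns
  bad <- setdiff(reaction_ids, lp$rxns)
  if (length(bad))
    stop("unknown reaction(s): ", paste(bad, collapse = ", "), call. = FALSE)
  objective_id <- if (lp$ec) model$base$objective else model$objective
  first <- fba(model, objective_id, "max")
  if (first$status != "optimal")
    stop("FVA requires an optimal base solution (status: ", first$status, ")",
         call. = FALSE)
  lb <- lp$lb; ub <- lp$ub
  j <- match(objective_id, lp$rxns)
  lb[j] <- max(lb[j], fraction_of_optimum * first$objective_value)
  one <- function(rid, maximize) {
    obj <- as.numeric(lp$rxns == rid)
    res <- solve_lp(obj, Aeq = lp$S, beq = rep(0, nrow(lp$S)),
                    Ale = if (lp$ec) matrix(lp$pool, 1) else NULL,
                    ble = lp$pool_bound, lb = lb, ub = ub, maximize = maximize)
    if (res$status != "optimal")
      stop("FVA subproblem ", rid, " not optimal: ", res$status, call. = FALSE)
    res$objective
  }
  v_min <- vapply(reaction_ids, one, numeric(1), maximize = FALSE)
  v_max <- vapply(reaction_ids, one, numeric(1), maximize = TRUE)
  data.frame(reaction_id = reaction_ids, v_min = v_min,
             v_max = pmax(v_max, v_min), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Aggregate split-model variability to original reactions
#'
#' Within a direction, isozyme copies are aggregated by the maximal copy
#' range `FV = max_j (v_max_j - v_min_j)`; across directions the reverse
#' range is subtracted from the forward range, clamped at zero (a negative
#' difference is logged).  An alternative net-flux aggregation
#' (`max(v_f) + max(v_r) - min(v_f) - min(v_r)` on the summed copies) is
#' available via `rule = "net"`.
#'
#' @param raw data.frame from [fva_raw()] covering all split copies.
#' @param split_map a `SplitMap`.
#' @param rule `"directional"` (default; subtract the reverse-direction
#'   range) or `"net"` (range of the net flux).
#' @return data.frame with columns `reaction_id`, `v_min`, `v_max`, `fv`.
#' @export
aggregate_variability <- function(raw, split_map, rule = c("directional", "net")) {
  rule <- match.arg(rule)
  idx <- stats::setNames(seq_len(nrow(raw)), raw$reaction_id)
  rng <- function(ids) {
    miss <- setdiff(ids, names(idx))
    if (length(miss))
      stop("raw ranges missing for split cop(ies): ",
           paste(miss, collapse = ", "), call. = FALSE)
    raw[idx[ids], , drop = FALSE]
  }
  rows <- lapply(names(split_map$forward_of), function(orig) {
    s <- split_ids_of(split_map, orig)
    fw <- rng(s$fwd)
    fv_fwd <- max(fw$v_max - fw$v_min)
    k <- which.max(fw$v_max - fw$v_min)
    v_min <- fw$v_min[k]; v_max <- fw$v_max[k]
    if (!length(s$rev)) {
      fv <- fv_fwd
    } else {
      rv <- rng(s$rev)
      fv_rev <- max(rv$v_max - rv$v_min)
      if (rule == "directional") {
        fv <- fv_fwd - fv_rev
        if (fv < 0) {
          if (fv < -1e-9)
            message(orig, ": reverse range exceeds forward range (",
                    signif(fv, 3), "); clamped to 0")
          fv <- 0
        }
      } else {
        # net-flux range of (sum fwd - sum rev) under independent ranges
        fv <- (sum(fw$v_max) - sum(fw$v_min)) + (sum(rv$v_max) - sum(rv$v_min))
      }
      v_min <- v_min - rv$v_max[which.max(rv$v_max - rv$v_min)]
    }
    data.frame(reaction_id = orig, v_min = v_min, v_max = v_max, fv = fv,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bound the uptake rate of an exchange reaction
#'
#' In the original orientation uptake is a negative exchange flux (the lower
#' bound is set to `-rate`); on a split model uptake is carried by the
#' `"<id>_reverse"` copy, whose upper bound is set to `rate`.
#'
#' @param model a `MetabolicModel` or `ECModel`.
#' @param exchange_id exchange reaction id (original, pre-split).
#' @param rate maximum uptake, mmol/gDW/h (>= 0).
#' @return the modified model.
#' @export
set_uptake <- function(model, exchange_id, rate) {
  base <- if (inherits(model, "ECModel")) model$base else model
  ids <- names(base$reactions)
  rev_id <- paste0(exchange_id, "_reverse")
  if (rev_id %in% ids) {
    set_bounds(model, rev_id, lb = 0, ub = rate)
  } else if (exchange_id %in% ids) {
    r <- base$reactions[[exchange_id]]
    if (r$lower_bound < 0) {
      # original orientation: uptake is negative flux
      set_bounds(model, exchange_id, lb = -rate)
    } else if (length(r$stoichiometry) == 1L && r$stoichiometry > 0) {
      # source reaction written in the import direction
      set_bounds(model, exchange_id, lb = 0, ub = rate)
    } else {
      # irreversible secretion-only exchange: uptake is structurally zero
      model
    }
  } else {
    stop("unknown exchange reaction: ", exchange_id, call. = FALSE)
  }
}

#' Phenotype phase plane
#'
#' Growth (pFBA objective) over a 2-D grid of substrate and oxygen uptake
#' bounds. Infeasible cells are recorded as 0.
#'
#' @param model a `MetabolicModel` or `ECModel`.
#' @param substrate_exchange_id,o2_exchange_id exchange reaction ids.
#' @param substrate_range,o2_range `c(min, max)` uptake bounds, mmol/gDW/h.
#' @param steps grid size; a single integer or `c(substrate, o2)`.
#' @return a matrix of growth rates with substrate values as rows (dimnames
#'   carry the uptake rates).
#' @export
phpp <- function(model, substrate_exchange_id, substrate_range = c(0, 10),
                 o2_exchange_id, o2_range = c(0, 50), steps = 21L) {
  steps <- rep_len(as.integer(steps), 2L)
  svals <- seq(substrate_range[1], substrate_range[2], length.out = steps[1])
  ovals <- seq(o2_range[1], o2_range[2], length.out = steps[2])
  grid <- matrix(0, steps[1], steps[2],
                 dimnames = list(format(svals, trim = TRUE),
                                 format(ovals, trim = TRUE)))
  for (i in seq_along(svals)) {
    mi <- set_uptake(model, substrate_exchange_id, svals[i])
    for (k in seq_along(ovals)) {
      mk <- set_uptake(mi, o2_exchange_id, ovals[k])
      sol <- pfba(mk)
      grid[i, k] <- if (sol$status == "optimal") max(sol$objective_value, 0) else 0
    }
  }
  grid
}
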