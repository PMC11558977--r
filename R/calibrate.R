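# Iterative kcat calibration.
#
# Both procedures only ever raise kcat values (they relax the pool
# constraint): the enzyme-usage method targets a measured growth rate by
# repeatedly relaxing the reaction that consumes the largest share of the
# enzyme pool; the 13C-consistency method raises kcats of reactions whose
# predicted net fluxes fall short of measured values.

# internal: one calibration step record
calib_step <- function(iteration, reaction_id, old_kcat, new_kcat, criterion,
                       metric_after, flag = NA_character_) {
  data.frame(iteration = iteration, reaction_id = reaction_id,
             old_kcat = old_kcat, new_kcat = new_kcat, criterion = criterion,
             metric_after = metric_after, flag = flag,
             stringsAsFactors = FALSE)
}

# internal: multiply one entry's kcat, capped, tag as calibrated
bump_kcat <- function(ec, rid, factor, cap) {
  e <- ec$enzymes[[rid]]
  e$kcat <- min(e$kcat * factor, cap)
  e$source <- "calibrated"
  ec$enzymes[[rid]] <- e
  ec
}

#' Apply named uptake bounds to a model
#'
#' @param model a `MetabolicModel` or `ECModel`.
#' @param conditions named list/vector, exchange id -> uptake rate; see
#'   [set_uptake()].
#' @return the modified model.
#' @export
apply_conditions <- function(model, conditions) {
  for (ex in names(conditions))
    model <- set_uptake(model, ex, conditions[[ex]])
  model
}

#' Calibrate kcats by the enzyme-usage method
#'
#' Repeatedly solves pFBA; while the growth rate is below
#' `target_growth * (1 - growth_tol)`, the kcat of the reaction with the
#' largest enzyme-usage share is multiplied by `factor` (ties broken by
#' reaction id). Terminates on convergence, `max_iter`, or stagnation (no
#' growth improvement > 1e-9 over 3 consecutive steps); the latter two are
#' flagged in the step log, not raised.
#'
#' @param ec an `ECModel`.
#' @param target_growth measured growth rate, 1/h.
#' @param conditions named list/vector of uptake bounds, exchange id -> rate.
#' @param factor multiplicative kcat update (> 1).
#' @param max_iter iteration cap.
#' @param growth_tol relative convergence tolerance on the growth rate.
#' @param kcat_cap upper cap on calibrated kcats, 1/s.
#' @return `list(model = calibrated ECModel, steps = data.frame,
#'   converged = logical, growth = achieved growth)`.
#' @export
calibrate_enzyme_usage <- function(ec, target_growth, conditions = list(),
                                   factor = 2, max_iter = 100L,
                                   growth_tol = 0.05, kcat_cap = 1e6) {
  stopifnot(target_growth > 0, factor > 1)
  ec <- apply_conditions(ec, conditions)
  steps <- list()
  stagnant <- 0L
  last_growth <- -Inf
  for (it in seq_len(max_iter + 1L)) {
    sol <- pfba(ec)
    if (sol$status != "optimal")
      stop("model infeasible under the calibration conditions", call. = FALSE)
    growth <- sol$objective_value
    if (growth >= target_growth * (1 - growth_tol)) {
      return(list(model = ec, steps = bind_steps(steps), converged = TRUE,
                  growth = growth))
    }
    if (it > max_iter) break
    if (growth <= last_growth + 1e-9) stagnant <- stagnant + 1L else stagnant <- 0L
    if (stagnant >= 3L) {
      steps[[length(steps) + 1L]] <-
        calib_step(it, NA_character_, NA_real_, NA_real_, "enzyme_usage",
                   growth, flag = "stagnation")
      return(list(model = ec, steps = bind_steps(steps), converged = FALSE,
                  growth = growth))
    }
    last_growth <- growth
    usage <- sol$enzyme_usage
    usage <- usage[names(usage) %in% names(ec$enzymes)]
    if (!length(usage) || sum(usage) <= 0) {
      steps[[length(steps) + 1L]] <-
        calib_step(it, NA_character_, NA_real_, NA_real_, "enzyme_usage",
                   growth, flag = "no_enzyme_usage")
      return(list(model = ec, steps = bind_steps(steps), converged = FALSE,
                  growth = growth))
    }
    ord <- order(-usage, names(usage))
    rid <- names(usage)[ord[1L]]
    old <- ec$enzymes[[rid]]$kcat
    ec <- bump_kcat(ec, rid, factor, kcat_cap)
    sol2 <- pfba(ec)
    g2 <- if (sol2$status == "optimal") sol2$objective_value else NA_real_
    # if this step overshoots the target band, bisect the step size so the
    # calibrated model ends within +/- growth_tol of the target (growth is
    # monotone in any single kcat)
    if (!is.na(g2) && g2 > target_growth * (1 + growth_tol)) {
      lo <- 1; hi <- factor
      for (b in 1:30) {
        mid <- (lo + hi) / 2
        ec$enzymes[[rid]]$kcat <- min(old * mid, kcat_cap)
        gm <- pfba(ec)$objective_value
        if (gm > target_growth * (1 + growth_tol)) hi <- mid
        else if (gm < target_growth * (1 - growth_tol)) lo <- mid
        else break
      }
      g2 <- pfba(ec)$objective_value
    }
    steps[[length(steps) + 1L]] <-
      calib_step(it, rid, old, ec$enzymes[[rid]]$kcat, "enzyme_usage", g2)
  }
  steps[[length(steps) + 1L]] <-
    calib_step(max_iter, NA_character_, NA_real_, NA_real_, "enzyme_usage",
               last_growth, flag = "max_iter")
  list(model = ec, steps = bind_steps(steps), converged = FALSE,
       growth = last_growth)
}

bind_steps <- function(steps) {
  if (!length(steps))
    return(data.frame(iteration = integer(0), reaction_id = character(0),
                      old_kcat = numeric(0), new_kcat = numeric(0),
                      criterion = character(0), metric_after = numeric(0),
                      flag = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, steps)
  rownames(out) <- NULL
  out
}

#' Calibrate kcats against measured 13C fluxes
#'
#' Repeatedly solves pFBA and maps the solution to net original-model fluxes.
#' Measurements with relative error above tolerance and an under-predicted
#' flux are candidate fixes. Per iteration, the candidate whose enzyme-cost-
#' dominant split copy consumes the largest share of the enzyme pool in the
#' current solution has that copy's kcat multiplied by `factor` (ties broken
#' by reaction id); selecting by realized enzyme usage targets the actual
#' kinetic bottleneck and avoids runaway relaxation of enzymes that are
#' merely downstream of it -- kcats are never lowered again. Over-predicted
#' fluxes are left alone (the pool row is an upper bound; over-prediction
#' signals network structure, not kcat).
#'
#' @param ec an `ECModel`.
#' @param measurements data.frame with columns `reaction_id` (original-model
#'   ids), `flux_mmol_gdw_h`, `rel_tolerance`.
#' @param split_map the `SplitMap` relating original to split ids.
#' @param conditions named uptake bounds, exchange id -> rate.
#' @param factor multiplicative kcat update (> 1).
#' @param max_iter iteration cap.
#' @param kcat_cap upper cap on calibrated kcats, 1/s.
#' @return `list(model = , steps = , converged = , errors = named relative
#'   errors after the final iteration)`.
#' @export
calibrate_c13 <- function(ec, measurements, split_map, conditions = list(),
                          factor = 2, max_iter = 100L, kcat_cap = 1e6) {
  stopifnot(factor > 1)
  eps <- 1e-6
  unknown <- setdiff(measurements$reaction_id, names(split_map$forward_of))
  if (length(unknown))
    stop("measurement(s) for unknown reaction id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  ec <- apply_conditions(ec, conditions)
  meas <- measurements$flux_mmol_gdw_h
  errors_of <- function(model) {
    sol <- pfba(model)
    if (sol$status != "optimal") return(NULL)
    pred <- net_fluxes(sol$fluxes, split_map)[measurements$reaction_id]
    list(pred = pred, err = abs(pred - meas) / pmax(abs(meas), eps),
         usage = sol$enzyme_usage)
  }
  # enzyme-cost-dominant split copy of a measured reaction
  dominant_copy <- function(model, orig) {
    s <- split_ids_of(split_map, orig)
    cands <- intersect(c(s$fwd, s$rev), names(model$enzymes))
    if (!length(cands)) return(NA_character_)
    coefs <- pool_coefficients(model)[cands]
    cands[order(-coefs, cands)[1L]]
  }
  steps <- list()
  stagnant <- 0L
  last_err <- Inf
  cur <- errors_of(ec)
  if (is.null(cur))
    stop("model infeasible under the calibration conditions", call. = FALSE)
  for (it in seq_len(max_iter)) {
    offending <- which(cur$err > measurements$rel_tolerance & cur$pred < meas)
    if (!length(offending)) {
      converged <- all(cur$err <= measurements$rel_tolerance)
      return(list(model = ec, steps = bind_steps(steps), converged = converged,
                  errors = stats::setNames(cur$err, measurements$reaction_id)))
    }
    mean_err <- mean(cur$err)
    if (mean_err >= last_err - 1e-9) stagnant <- stagnant + 1L else stagnant <- 0L
    if (stagnant >= 6L) {
      steps[[length(steps) + 1L]] <-
        calib_step(it, NA_character_, NA_real_, NA_real_, "c13_consistency",
                   mean_err, flag = "stagnation")
      return(list(model = ec, steps = bind_steps(steps), converged = FALSE,
                  errors = stats::setNames(cur$err, measurements$reaction_id)))
    }
    last_err <- mean_err
    cands <- vapply(offending, function(k)
      dominant_copy(ec, measurements$reaction_id[k]), character(1))
    keep <- !is.na(cands) &
      vapply(cands, function(r) is.na(r) || ec$enzymes[[r]]$kcat < kcat_cap,
             logical(1))
    cands <- unique(cands[keep])
    if (!length(cands)) {
      steps[[length(steps) + 1L]] <-
        calib_step(it, NA_character_, NA_real_, NA_real_, "c13_consistency",
                   mean_err, flag = "stagnation")
      return(list(model = ec, steps = bind_steps(steps), converged = FALSE,
                  errors = stats::setNames(cur$err, measurements$reaction_id)))
    }
    usage <- cur$usage[cands]
    usage[is.na(usage)] <- 0
    rid <- cands[order(-usage, cands)[1L]]
    old <- ec$enzymes[[rid]]$kcat
    ec <- bump_kcat(ec, rid, factor, kcat_cap)
    steps[[length(steps) + 1L]] <-
      calib_step(it, rid, old, ec$enzymes[[rid]]$kcat, "c13_consistency",
                 mean_err)
    cur <- errors_of(ec)
    if (is.null(cur))
      stop("model became infeasible during calibration", call. = FALSE)
  }
  steps[[length(steps) + 1L]] <-
    calib_step(max_iter, NA_character_, NA_real_, NA_real_, "c13_consistency",
               mean(cur$err), flag = "max_iter")
  list(model = ec, steps = bind_steps(steps), converged = FALSE,
       errors = stats::setNames(cur$err, measurements$reaction_id))
}
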