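# Core data model: metabolites, reactions, and constraint-based models.
#
# A MetabolicModel is a plain list with class "MetabolicModel":
#   metabolites : data.frame(id, name, compartment, formula, carbon_count)
#   reactions   : named list; each element a list(id, name, stoichiometry
#                 (named numeric, metabolite id -> coefficient), lower_bound,
#                 upper_bound, gpr (string), subsystem)
#   genes       : data.frame(id, protein, mw_kda)
#   objective   : reaction id whose flux is the optimization objective
# Fluxes are mmol/gDW/h throughout; the biomass reaction flux is the growth
# rate in 1/h.

#' Create a metabolite
#'
#' @param id,name,compartment identifier, display name and compartment tag.
#' @param formula optional chemical formula (e.g. `"C6H12O6"`).
#' @param carbon_count optional carbon atom count; derived from `formula`
#'   when omitted.
#' @return a one-row data.frame.
#' @export
metabolite <- function(id, name = id, compartment = "c", formula = NA_character_,
                       carbon_count = NA_integer_) {
  if (is.na(carbon_count) && !is.na(formula))
    carbon_count <- count_carbons(formula)
  data.frame(id = id, name = name, compartment = compartment,
             formula = formula, carbon_count = as.integer(carbon_count),
             stringsAsFactors = FALSE)
}

#' Carbon atoms implied by a chemical formula
#' @param formula formula string such as `"C6H12O6"`.
#' @return integer carbon count (0 if no C atom).
#' @export
count_carbons <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) return(NA_integer_)
  m <- gregexpr("C(?![a-z])([0-9]*)", formula, perl = TRUE)[[1]]
  if (m[1] == -1L) return(0L)
  total <- 0L
  for (i in seq_along(m)) {
    frag <- substr(formula, m[i], m[i] + attr(m, "match.length")[i] - 1L)
    num <- sub("^C", "", frag)
    total <- total + if (nzchar(num)) as.integer(num) else 1L
  }
  total
}

#' Create a reaction
#'
#' @param id,name identifier and display name.
#' @param stoichiometry named numeric vector, metabolite id to signed
#'   coefficient (negative = consumed). Zero coefficients are dropped.
#' @param lower_bound,upper_bound flux bounds in mmol/gDW/h.
#' @param gpr gene-protein-reaction rule string ('' = spontaneous).
#' @param subsystem optional subsystem label.
#' @return a reaction list.
#' @export
reaction <- function(id, stoichiometry, lower_bound = 0, upper_bound = 1000,
                     name = id, gpr = "", subsystem = NA_character_) {
  stoichiometry <- stoichiometry[stoichiometry != 0]
  list(id = id, name = name, stoichiometry = stoichiometry,
       lower_bound = as.numeric(lower_bound),
       upper_bound = as.numeric(upper_bound),
       gpr = gpr, subsystem = subsystem)
}

#' Create a metabolic model
#'
#' @param metabolites data.frame as produced by row-binding [metabolite()].
#' @param reactions list of reactions from [reaction()].
#' @param genes data.frame with columns `id`, and optionally `protein`
#'   (accession) and `mw_kda`; genes referenced by GPRs but not listed are
#'   added automatically with NA annotation.
#' @param objective id of the objective (typically biomass) reaction.
#' @param validate check model invariants and fail on findings.
#' @return an object of class `MetabolicModel`.
#' @export
metabolic_model <- function(metabolites, reactions, genes = NULL, objective,
                            validate = TRUE) {
  names(reactions) <- vapply(reactions, `[[`, character(1), "id")
  used_genes <- sort(unique(unlist(lapply(reactions, function(r) gpr_genes(r$gpr)))))
  if (is.null(genes)) {
    genes <- data.frame(id = used_genes,
                        protein = rep(NA_character_, length(used_genes)),
                        mw_kda = rep(NA_real_, length(used_genes)),
                        stringsAsFactors = FALSE)
  } else {
    if (!"protein" %in% names(genes)) genes$protein <- NA_character_
    if (!"mw_kda" %in% names(genes)) genes$mw_kda <- NA_real_
    missing <- setdiff(used_genes, genes$id)
    if (length(missing))
      genes <- rbind(genes,
                     data.frame(id = missing,
                                protein = rep(NA_character_, length(missing)),
                                mw_kda = rep(NA_real_, length(missing)),
                                stringsAsFactors = FALSE))
  }
  model <- structure(list(metabolites = metabolites, reactions = reactions,
                          genes = genes, objective = objective),
                     class = "MetabolicModel")
  if (validate) {
    findings <- validate_model(model)
    if (length(findings))
      stop("invalid model:\n  ", paste(findings, collapse = "\n  "), call. = FALSE)
  }
  model
}

#' @export
print.MetabolicModel <- function(x, ...) {
  cat("MetabolicModel:", length(x$reactions), "reactions,",
      nrow(x$metabolites), "metabolites,", nrow(x$genes), "genes\n")
  cat("objective:", x$objective, "\n")
  invisible(x)
}

#' Reaction ids of a model
#' @param model a `MetabolicModel` or `ECModel`.
#' @return character vector.
#' @export
rxn_ids <- function(model) {
  if (inherits(model, "ECModel")) model <- model$base
  names(model$reactions)
}

#' Metabolite ids of a model
#' @param model a `MetabolicModel` or `ECModel`.
#' @return character vector.
#' @export
met_ids <- function(model) {
  if (inherits(model, "ECModel")) model <- model$base
  model$metabolites$id
}

#' Stoichiometric matrix
#'
#' @param model a `MetabolicModel` or `ECModel`.
#' @return dense numeric matrix, metabolites x reactions, with dimnames.
#' @export
stoich_matrix <- function(model) {
  if (inherits(model, "ECModel")) model <- model$base
  mids <- model$metabolites$id
  rids <- names(model$reactions)
  S <- matrix(0, length(mids), length(rids), dimnames = list(mids, rids))
  for (j in seq_along(rids)) {
    st <- model$reactions[[j]]$stoichiometry
    S[names(st), j] <- st
  }
  S
}

#' Exchange reactions of a model
#'
#' Exchanges are identified structurally: reactions whose stoichiometry
#' touches exactly one metabolite.  In the original orientation uptake is a
#' negative exchange flux; after [to_irreversible()] uptake is carried by the
#' `_reverse` copy.
#'
#' @param model a `MetabolicModel` or `ECModel`.
#' @return character vector of reaction ids.
#' @export
exchange_reactions <- function(model) {
  if (inherits(model, "ECModel")) model <- model$base
  ids <- names(model$reactions)
  ids[vapply(model$reactions, function(r) length(r$stoichiometry) == 1L, logical(1))]
}

#' Validate a model
#'
#' Checks id uniqueness, bound ordering, dangling metabolite/gene references,
#' zero stoichiometric coefficients, objective existence and formula/carbon
#' consistency.  Returns findings rather than raising.
#'
#' @param model a `MetabolicModel`.
#' @return character vector of findings; empty iff the model is valid.
#' @export
validate_model <- function(model) {
  findings <- character(0)
  mids <- model$metabolites$id
  rids <- names(model$reactions)
  if (anyDuplicated(mids))
    findings <- c(findings, paste("duplicate metabolite id:",
                                  paste(unique(mids[duplicated(mids)]), collapse = ", ")))
  if (anyDuplicated(rids))
    findings <- c(findings, paste("duplicate reaction id:",
                                  paste(unique(rids[duplicated(rids)]), collapse = ", ")))
  if (anyDuplicated(model$genes$id))
    findings <- c(findings, "duplicate gene id")
  if (!model$objective %in% rids)
    findings <- c(findings, paste("objective reaction not found:", model$objective))
  for (r in model$reactions) {
    if (r$lower_bound > r$upper_bound)
      findings <- c(findings, paste0(r$id, ": lower_bound > upper_bound"))
    if (any(r$stoichiometry == 0))
      findings <- c(findings, paste0(r$id, ": zero stoichiometric coefficient"))
    dangling <- setdiff(names(r$stoichiometry), mids)
    if (length(dangling))
      findings <- c(findings, paste0(r$id, ": undeclared metabolite ",
                                     paste(dangling, collapse = ", ")))
    bad_genes <- setdiff(tryCatch(gpr_genes(r$gpr), error = function(e) character(0)),
                         model$genes$id)
    if (length(bad_genes))
      findings <- c(findings, paste0(r$id, ": undeclared gene ",
                                     paste(bad_genes, collapse = ", ")))
  }
  cc <- model$metabolites$carbon_count
  ff <- model$metabolites$formula
  for (i in seq_along(mids)) {
    if (!is.na(cc[i]) && !is.na(ff[i])) {
      implied <- count_carbons(ff[i])
      if (!is.na(implied) && implied != cc[i])
        findings <- c(findings, paste0(mids[i], ": carbon_count ", cc[i],
                                       " != formula-implied ", implied))
    }
  }
  findings
}

# internal: bounds as a 2-column matrix
model_bounds <- function(model) {
  if (inherits(model, "ECModel")) model <- model$base
  lb <- vapply(model$reactions, `[[`, numeric(1), "lower_bound")
  ub <- vapply(model$reactions, `[[`, numeric(1), "upper_bound")
  cbind(lb = lb, ub = ub)
}

#' Set reaction bounds
#'
#' @param model a `MetabolicModel` or `ECModel`.
#' @param rxn_id reaction id.
#' @param lb,ub new bounds (either may be omitted).
#' @return the modified model.
#' @export
set_bounds <- function(model, rxn_id, lb = NULL, ub = NULL) {
  target <- if (inherits(model, "ECModel")) "base" else NULL
  get_m <- function() if (is.null(target)) model else model$base
  m <- get_m()
  if (!rxn_id %in% names(m$reactions))
    stop("unknown reaction id: ", rxn_id, call. = FALSE)
  if (!is.null(lb)) m$reactions[[rxn_id]]$lower_bound <- lb
  if (!is.null(ub)) m$reactions[[rxn_id]]$upper_bound <- ub
  if (is.null(target)) m else { model$base <- m; model }
}
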