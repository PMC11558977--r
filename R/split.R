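# Structural transformations preceding enzyme-constraint integration:
# reversible reactions become forward/reverse pairs, and reactions catalyzed
# by isozymes ('or' in the GPR) are segregated into one copy per isozyme.
# A SplitMap records how post-split reaction ids relate to the original ids
# so that solutions can be mapped back to net fluxes.

new_split_map <- function(forward_of, reverse_of, isozyme_copies) {
  structure(list(forward_of = forward_of, reverse_of = reverse_of,
                 isozyme_copies = isozyme_copies),
            class = "SplitMap")
}

#' @export
print.SplitMap <- function(x, ...) {
  n_rev <- sum(!vapply(x$reverse_of, is.null, logical(1)))
  n_iso <- sum(vapply(x$isozyme_copies, length, integer(1)) > 1L)
  cat("SplitMap:", length(x$forward_of), "original reactions,",
      n_rev, "reversible,", n_iso, "with isozyme copies\n")
  invisible(x)
}

#' Split reversible reactions into irreversible pairs
#'
#' Each reaction with a negative lower bound yields a forward copy (same id,
#' bounds `[0, ub]`) and a reverse copy (`"<id>_reverse"`, negated
#' stoichiometry, bounds `[0, -lb]`). Already-irreversible reactions pass
#' through unchanged, so the operation is idempotent.
#'
#' @param model a `MetabolicModel`.
#' @return `list(model = , split_map = )`.
#' @export
to_irreversible <- function(model) {
  fwd <- list(); rev <- list(); iso <- list()
  out <- list()
  for (r in model$reactions) {
    fwd[[r$id]] <- r$id
    iso[[r$id]] <- r$id
    if (r$lower_bound < 0) {
      f <- r
      f$lower_bound <- 0
      f$upper_bound <- max(r$upper_bound, 0)
      rid <- paste0(r$id, "_reverse")
      b <- r
      b$id <- rid
      b$name <- paste0(r$name, " (reverse)")
      b$stoichiometry <- -r$stoichiometry
      b$lower_bound <- max(-r$upper_bound, 0)
      b$upper_bound <- -r$lower_bound
      out[[r$id]] <- f
      out[[rid]] <- b
      rev[[r$id]] <- rid
    } else {
      out[[r$id]] <- r
    }
  }
  m2 <- model
  m2$reactions <- out
  list(model = m2, split_map = new_split_map(fwd, rev, iso))
}

#' Segregate isozyme-catalyzed reactions into separate copies
#'
#' A reaction whose GPR is (equivalent to) an 'or' of k conjuncts becomes k
#' reactions `"<id>_num1"` ... `"<id>_numk"` with identical stoichiometry and
#' bounds, each carrying one 'and'-complex as its GPR, in the textual order
#' of the conjuncts. Single-conjunct reactions pass through unchanged.
#'
#' @param model a `MetabolicModel`.
#' @return `list(model = , split_map = )`.
#' @export
expand_isozymes <- function(model) {
  fwd <- list(); rev <- list(); iso <- list()
  out <- list()
  for (r in model$reactions) {
    dnf <- tryCatch(gpr_to_dnf(r$gpr),
                    error = function(e) stop("reaction ", r$id, ": ",
                                             conditionMessage(e), call. = FALSE))
    fwd[[r$id]] <- r$id
    if (length(dnf) <= 1L) {
      iso[[r$id]] <- r$id
      out[[r$id]] <- r
    } else {
      if (identical(r$id, model$objective))
        warning("objective reaction ", r$id,
                " has isozymes; first copy keeps the objective")
      ids <- paste0(r$id, "_num", seq_along(dnf))
      iso[[r$id]] <- ids
      for (k in seq_along(dnf)) {
        cp <- r
        cp$id <- ids[k]
        cp$gpr <- paste(dnf[[k]], collapse = " and ")
        out[[ids[k]]] <- cp
      }
    }
  }
  m2 <- model
  m2$reactions <- out
  if (!model$objective %in% names(out)) {
    m2$objective <- iso[[model$objective]][1L]
  }
  list(model = m2, split_map = new_split_map(fwd, rev, iso))
}

#' Full split: irreversible pairs, then isozyme copies
#'
#' The canonical pre-processing for enzyme-constrained models. Reverse copies
#' are created first so that each direction is expanded independently.
#'
#' @param model a `MetabolicModel`.
#' @return `list(model = , split_map = )` with a composed map from original
#'   reaction ids to all split ids.
#' @export
split_model <- function(model) {
  s1 <- to_irreversible(model)
  s2 <- expand_isozymes(s1$model)
  list(model = s2$model,
       split_map = compose_split_maps(s1$split_map, s2$split_map))
}

#' Compose two split maps applied in sequence
#'
#' @param first,second `SplitMap`s; `second` must be keyed by the output ids
#'   of `first`.
#' @return a composed `SplitMap` keyed by the original ids.
#' @export
compose_split_maps <- function(first, second) {
  lookup <- function(id) {
    if (!is.null(second$isozyme_copies[[id]])) second$isozyme_copies[[id]] else id
  }
  iso <- list()
  rev <- list()
  for (orig in names(first$forward_of)) {
    iso[[first$forward_of[[orig]]]] <- lookup(first$forward_of[[orig]])
    rv <- first$reverse_of[[orig]]
    if (!is.null(rv)) {
      iso[[rv]] <- lookup(rv)
      rev[[orig]] <- rv
    }
  }
  new_split_map(first$forward_of, rev, iso)
}

# internal: split ids carrying an original reaction's forward / reverse flux
split_ids_of <- function(split_map, orig) {
  f <- split_map$forward_of[[orig]]
  if (is.null(f)) stop("unknown original reaction id: ", orig, call. = FALSE)
  fwd <- if (!is.null(split_map$isozyme_copies[[f]])) split_map$isozyme_copies[[f]] else f
  rv <- split_map$reverse_of[[orig]]
  rev <- if (is.null(rv)) character(0) else {
    if (!is.null(split_map$isozyme_copies[[rv]])) split_map$isozyme_copies[[rv]] else rv
  }
  list(fwd = fwd, rev = rev)
}

#' Map split-model fluxes back to net original-model fluxes
#'
#' Net flux of an original reaction = sum of its forward copies' fluxes minus
#' the sum of its reverse copies'.
#'
#' @param fluxes named numeric vector of split-model fluxes.
#' @param split_map a `SplitMap`.
#' @return named numeric vector over original reaction ids.
#' @export
net_fluxes <- function(fluxes, split_map) {
  origs <- names(split_map$forward_of)
  known <- unique(unlist(lapply(origs, function(o) {
    s <- split_ids_of(split_map, o); c(s$fwd, s$rev)
  })))
  unknown <- setdiff(names(fluxes), known)
  if (length(unknown))
    stop("flux entries for unknown split ids: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  get <- function(ids) sum(fluxes[ids[ids %in% names(fluxes)]])
  out <- vapply(origs, function(o) {
    s <- split_ids_of(split_map, o)
    get(s$fwd) - get(s$rev)
  }, numeric(1))
  stats::setNames(out, origs)
}
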