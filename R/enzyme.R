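# The enzyme layer: per-reaction kcat/MW/saturation data, the proteome
# enzyme mass fraction, and assembly of the enzyme-constrained model.
#
# The pool constraint bounds the total enzyme mass implied by fluxes:
#     sum_i  v_i * MW_i / (sigma_i * kcat_i * 3600)  <=  ptot * f
# with v in mmol/gDW/h, MW in kDa (= g/mmol), kcat in 1/s (the 3600 converts
# to 1/h), sigma the saturation coefficient, ptot the total protein fraction
# of dry weight (g/gDW) and f the enzyme mass fraction of total protein.

KCAT_SOURCES <- c("calibrated", "database", "turnup_predicted", "dl_predicted",
                  "imputed")

#' Enzyme mass fraction of a proteome
#'
#' The fraction f of total protein mass contributed by proteins present in
#' the metabolic model: `sum(A_i * MW_i over model proteins) /
#' sum(A_j * MW_j over the whole proteome)`, with A the mole-ratio abundances.
#'
#' @param proteome data.frame with columns `protein_id`,
#'   `abundance_mole_ratio` and `mw_kda`.
#' @param model_protein_ids character vector of proteins carried by the model.
#' @return the mass fraction, in `[0, 1]`.
#' @export
enzyme_mass_fraction <- function(proteome, model_protein_ids) {
  if (is.null(proteome) || nrow(proteome) == 0L)
    stop("empty proteome", call. = FALSE)
  mass <- proteome$abundance_mole_ratio * proteome$mw_kda
  denom <- sum(mass)
  if (denom <= 0) stop("proteome has zero total mass", call. = FALSE)
  absent <- setdiff(model_protein_ids, proteome$protein_id)
  if (length(absent))
    message(length(absent), " model protein(s) absent from the proteome; ",
            "excluded from the numerator")
  sum(mass[proteome$protein_id %in% model_protein_ids]) / denom
}

#' Assembled molecular weight of an enzyme complex
#'
#' @param complex data.frame with columns `gene_id`, `subunit_count` and
#'   `subunit_mw` (kDa). Missing counts default to 1 with a message.
#' @return total complex MW in kDa.
#' @export
assemble_mw <- function(complex) {
  if (is.null(complex) || nrow(complex) == 0L)
    stop("empty enzyme complex", call. = FALSE)
  counts <- complex$subunit_count
  if (any(is.na(counts))) {
    message("missing subunit count(s) for ",
            paste(complex$gene_id[is.na(counts)], collapse = ", "),
            "; defaulting to 1")
    counts[is.na(counts)] <- 1L
  }
  if (any(counts < 1) || any(complex$subunit_mw <= 0))
    stop("subunit counts must be >= 1 and MWs > 0", call. = FALSE)
  sum(counts * complex$subunit_mw)
}

# internal: kcat lookup with post-split fallback. A record keyed by an
# original reaction id applies to all of its split copies.
kcat_candidate_keys <- function(rxn_id) {
  keys <- rxn_id
  base <- sub("_num[0-9]+$", "", rxn_id)
  if (base != rxn_id) keys <- c(keys, base)
  base2 <- sub("_reverse$", "", base)
  if (base2 != base) keys <- c(keys, base2)
  keys
}

#' Merge kcat records by source priority, with optional median imputation
#'
#' Per reaction, the record from the highest-priority source wins. Records
#' keyed by an original (pre-split) id apply to all split copies. Reactions
#' with no record receive the median of all directly covered values, tagged
#' `source = "imputed"` (or are absent with `imputation = "none"`).
#'
#' @param records data.frame with columns `reaction_id`, `kcat_s`, `source`.
#' @param source_priority character vector ordering the sources, best first;
#'   must cover every source present in `records`.
#' @param reactions character vector of (post-split) reaction ids to cover.
#' @param imputation `"median"` or `"none"`.
#' @return data.frame with columns `reaction_id`, `kcat_s`, `source`, one row
#'   per covered reaction.
#' @export
merge_kcat <- function(records,
                       source_priority = c("calibrated", "database",
                                           "turnup_predicted", "dl_predicted"),
                       reactions,
                       imputation = c("median", "none")) {
  imputation <- match.arg(imputation)
  if (nrow(records)) {
    unknown <- setdiff(unique(records$source), c(source_priority, "imputed"))
    if (length(unknown))
      stop("kcat sources not covered by the priority order: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    if (any(records$kcat_s <= 0))
      stop("kcat values must be positive", call. = FALSE)
  }
  pick <- function(rid) {
    for (key in kcat_candidate_keys(rid)) {
      hits <- records[records$reaction_id == key, , drop = FALSE]
      if (nrow(hits)) {
        hits <- hits[order(match(hits$source, source_priority)), , drop = FALSE]
        return(hits[1L, ])
      }
    }
    NULL
  }
  rows <- lapply(reactions, pick)
  covered <- !vapply(rows, is.null, logical(1))
  out <- do.call(rbind, rows[covered])
  if (!is.null(out)) out$reaction_id <- reactions[covered]
  if (any(!covered) && imputation == "median") {
    if (is.null(out))
      stop("no kcat records to impute a median from", call. = FALSE)
    med <- stats::median(out$kcat_s)
    out <- rbind(out, data.frame(reaction_id = reactions[!covered],
                                 kcat_s = med, source = "imputed",
                                 stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(reaction_id = character(0), kcat_s = numeric(0),
                      source = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(match(out$reaction_id, reactions)), , drop = FALSE]
}

#' Build per-reaction enzyme entries from kcat and subunit tables
#'
#' For each reaction of a split model with a single-conjunct GPR and a kcat
#' record, assembles the complex from the subunit table and attaches kcat and
#' saturation. Reactions with empty GPRs or no kcat are skipped (they carry
#' no enzyme cost).
#'
#' @param model a split (irreversible, isozyme-expanded) `MetabolicModel`.
#' @param kcat_table data.frame with columns `reaction_id`, `kcat_s`,
#'   `source` (pre- or post-split ids; see [merge_kcat()]).
#' @param subunit_table data.frame with columns `gene_id`, `subunit_mw_kda`,
#'   `subunit_count`.
#' @param sigma default saturation coefficient.
#' @param imputation passed to [merge_kcat()].
#' @return named list of enzyme entries keyed by reaction id.
#' @export
make_enzyme_entries <- function(model, kcat_table, subunit_table, sigma = 0.5,
                                imputation = "median") {
  enzymatic <- Filter(function(r) nzchar(r$gpr), model$reactions)
  kc <- merge_kcat(kcat_table, reactions = names(enzymatic),
                   imputation = imputation)
  kmap <- stats::setNames(seq_len(nrow(kc)), kc$reaction_id)
  entries <- list()
  for (r in enzymatic) {
    if (!r$id %in% names(kmap)) next
    genes <- gpr_genes(r$gpr)
    sub <- subunit_table[match(genes, subunit_table$gene_id), , drop = FALSE]
    if (any(is.na(sub$gene_id)))
      stop("no subunit data for gene(s) ",
           paste(genes[is.na(sub$gene_id)], collapse = ", "),
           " of reaction ", r$id, call. = FALSE)
    complex <- data.frame(gene_id = genes,
                          subunit_count = sub$subunit_count,
                          subunit_mw = sub$subunit_mw_kda,
                          stringsAsFactors = FALSE)
    rec <- kc[kmap[[r$id]], ]
    entries[[r$id]] <- enzyme_entry(r$id, complex, kcat = rec$kcat_s,
                                    sigma = sigma, source = rec$source)
  }
  entries
}

#' Create an enzyme entry
#'
#' @param reaction_id post-split reaction id.
#' @param complex data.frame with columns `gene_id`, `subunit_count`,
#'   `subunit_mw` (kDa).
#' @param kcat turnover number in 1/s.
#' @param sigma saturation coefficient in (0, 1].
#' @param source kcat provenance tag.
#' @return a list of class `enzyme_entry`.
#' @export
enzyme_entry <- function(reaction_id, complex, kcat, sigma = 0.5,
                         source = "database") {
  if (kcat <= 0) stop("kcat must be positive", call. = FALSE)
  if (sigma <= 0 || sigma > 1) stop("sigma must be in (0, 1]", call. = FALSE)
  structure(list(reaction_id = reaction_id, complex = complex,
                 assembled_mw = assemble_mw(complex), kcat = kcat,
                 sigma = sigma, source = source),
            class = "enzyme_entry")
}

#' Build an enzyme-constrained model
#'
#' Attaches enzyme entries and the proteome pool bound `ptot * f` to a split
#' model. The LP gains a single row `sum_i v_i * MW_i / (sigma_i * kcat_i *
#' 3600) <= ptot * f`; reactions without an entry contribute zero.
#'
#' @param model a split (irreversible, isozyme-expanded) `MetabolicModel`.
#' @param enzymes named list of [enzyme_entry()] keyed by reaction id.
#' @param ptot total protein fraction, g protein/gDW.
#' @param f enzyme mass fraction of total protein.
#' @param default_sigma saturation assigned to entries lacking one.
#' @param split_map optional `SplitMap` stored for downstream reporting.
#' @return an object of class `ECModel`.
#' @export
build_ec_model <- function(model, enzymes, ptot = 0.4653, f = 0.55,
                           default_sigma = 0.5, split_map = NULL) {
  if (any(model_bounds(model)[, "lb"] < 0))
    stop("model must be irreversible (run split_model() first)", call. = FALSE)
  if (ptot * f <= 0) stop("pool bound ptot * f must be positive", call. = FALSE)
  bad <- setdiff(names(enzymes), names(model$reactions))
  if (length(bad))
    stop("enzyme entries for unknown reaction(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  enzymes <- lapply(enzymes, function(e) {
    if (is.null(e$sigma) || is.na(e$sigma)) e$sigma <- default_sigma
    e
  })
  structure(list(base = model, enzymes = enzymes, ptot = ptot, f = f,
                 pool_bound = ptot * f, split_map = split_map),
            class = "ECModel")
}

#' @export
print.ECModel <- function(x, ...) {
  cat("ECModel:", length(x$base$reactions), "reactions,",
      length(x$enzymes), "with enzyme data\n")
  cat(sprintf("pool bound: %.6g g/gDW (ptot %.4g x f %.4g)\n",
              x$pool_bound, x$ptot, x$f))
  invisible(x)
}

#' Enzyme pool coefficients of an ECModel
#'
#' @param ec an `ECModel`.
#' @return named numeric vector over all reactions; `MW / (sigma * kcat *
#'   3600)` in g.h/mmol for enzymatic reactions, 0 otherwise.
#' @export
pool_coefficients <- function(ec) {
  coefs <- stats::setNames(numeric(length(ec$base$reactions)),
                           names(ec$base$reactions))
  for (e in ec$enzymes) {
    coefs[e$reaction_id] <- e$assembled_mw / (e$sigma * e$kcat * 3600)
  }
  coefs
}

#' Per-reaction enzyme usage of a flux distribution
#'
#' `E_i = v_i * MW_i / (sigma_i * kcat_i * 3600)` in g enzyme/gDW.
#'
#' @param ec an `ECModel`.
#' @param fluxes named numeric vector over the model's reactions.
#' @return `list(usage = named vector, total = scalar)`.
#' @export
enzyme_usage <- function(ec, fluxes) {
  coefs <- pool_coefficients(ec)
  enz <- names(ec$enzymes)
  missing <- setdiff(enz, names(fluxes))
  if (length(missing))
    stop("fluxes missing for enzymatic reaction(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (any(fluxes[enz] < -1e-9))
    stop("negative flux on an irreversible (split) model", call. = FALSE)
  usage <- coefs[names(fluxes)] * pmax(fluxes, 0)
  list(usage = usage, total = sum(usage))
}

# ---- ecModel serialization -------------------------------------------------

#' Write an ECModel as annotated COBRA JSON
#'
#' The base model is written in the COBRA dialect with per-reaction keys
#' `kcat_s`, `mw_kda`, `sigma`, `kcat_source` and a top-level `ec` block
#' holding `ptot` and `f`, plus the complex composition needed to rebuild
#' the entries.
#'
#' @param ec an `ECModel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ec_model <- function(ec, path) {
  model <- ec$base
  for (e in ec$enzymes) {
    model$reactions[[e$reaction_id]]$extra <-
      c(model$reactions[[e$reaction_id]]$extra,
        list(kcat_s = e$kcat, mw_kda = e$assembled_mw, sigma = e$sigma,
             kcat_source = e$source,
             complex = list(gene_id = e$complex$gene_id,
                            subunit_count = e$complex$subunit_count,
                            subunit_mw = e$complex$subunit_mw)))
  }
  model$extra <- c(model$extra, list(ec = list(ptot = ec$ptot, f = ec$f)))
  write_cobra_json(model, path)
  invisible(path)
}

#' Read an ECModel written by [write_ec_model()]
#'
#' @param path file path.
#' @return an `ECModel`.
#' @export
read_ec_model <- function(path) {
  model <- read_cobra_json(path)
  ecinfo <- model$extra$ec
  if (is.null(ecinfo))
    stop("not an ecModel file (missing top-level 'ec' block): ", path,
         call. = FALSE)
  enzymes <- list()
  for (r in model$reactions) {
    ex <- r$extra
    if (!is.null(ex$kcat_s)) {
      complex <- data.frame(gene_id = unlist(ex$complex$gene_id),
                            subunit_count = unlist(ex$complex$subunit_count),
                            subunit_mw = unlist(ex$complex$subunit_mw),
                            stringsAsFactors = FALSE)
      enzymes[[r$id]] <- enzyme_entry(r$id, complex, kcat = ex$kcat_s,
                                      sigma = ex$sigma, source = ex$kcat_source)
      keep <- setdiff(names(ex), c("kcat_s", "mw_kda", "sigma", "kcat_source",
                                   "complex"))
      model$reactions[[r$id]]$extra <- if (length(keep)) ex[keep] else NULL
    }
  }
  model$extra$ec <- NULL
  if (!length(model$extra)) model$extra <- NULL
  build_ec_model(model, enzymes, ptot = ecinfo$ptot, f = ecinfo$f)
}

# ---- tabular inputs --------------------------------------------------------

#' Read a kcat table
#'
#' CSV/TSV with columns `reaction_id`, `kcat_s`, `source`.
#' @param path file path; the delimiter is sniffed (tab vs comma).
#' @return data.frame.
#' @export
read_kcat_table <- function(path) {
  df <- read_delim_auto(path)
  need <- c("reaction_id", "kcat_s", "source")
  if (!all(need %in% names(df)))
    stop("kcat table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  df
}

#' Read an enzyme subunit table
#'
#' CSV/TSV with columns `gene_id`, `subunit_mw_kda`, `subunit_count`.
#' @param path file path.
#' @return data.frame.
#' @export
read_subunit_table <- function(path) {
  df <- read_delim_auto(path)
  need <- c("gene_id", "subunit_mw_kda", "subunit_count")
  if (!all(need %in% names(df)))
    stop("subunit table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  df
}

#' Read a proteomics abundance table
#'
#' CSV/TSV with columns `protein_id`, `abundance_mole_ratio`, `mw_kda`.
#' @param path file path.
#' @return data.frame.
#' @export
read_proteome_table <- function(path) {
  df <- read_delim_auto(path)
  need <- c("protein_id", "abundance_mole_ratio", "mw_kda")
  if (!all(need %in% names(df)))
    stop("proteome table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  df
}

#' Read a 13C flux measurement table
#'
#' CSV/TSV with columns `reaction_id`, `flux_mmol_gdw_h`, `rel_tolerance`.
#' @param path file path.
#' @return data.frame.
#' @export
read_measurements_table <- function(path) {
  df <- read_delim_auto(path)
  need <- c("reaction_id", "flux_mmol_gdw_h", "rel_tolerance")
  if (!all(need %in% names(df)))
    stop("measurements table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  df
}

read_delim_auto <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
}
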