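# Model readers and writers: COBRA-style JSON and SBML Level 3 with the FBC
# extension (bounds, objective and gene associations only).

#' Read a constraint-based model
#'
#' @param path file path.
#' @param format `"cobra-json"` or `"sbml"`; guessed from the file extension
#'   when omitted (`.json` vs `.xml`/`.sbml`).
#' @return a validated [`MetabolicModel`][metabolic_model].
#' @export
read_model <- function(path, format = c("guess", "cobra-json", "sbml")) {
  format <- match.arg(format)
  if (format == "guess") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "cobra-json" else "sbml"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(format,
         "cobra-json" = read_cobra_json(path),
         "sbml" = read_sbml(path))
}

#' Write a constraint-based model
#'
#' The emitted file re-reads to a field-for-field equal model.
#'
#' @param model a `MetabolicModel`.
#' @param path output file path.
#' @param format `"cobra-json"` or `"sbml"`; guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("guess", "cobra-json", "sbml")) {
  format <- match.arg(format)
  if (format == "guess") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "cobra-json" else "sbml"
  }
  switch(format,
         "cobra-json" = write_cobra_json(model, path),
         "sbml" = write_sbml(model, path))
  invisible(path)
}

# ---- COBRA JSON ------------------------------------------------------------

KNOWN_RXN_KEYS <- c("id", "name", "metabolites", "lower_bound", "upper_bound",
                    "gene_reaction_rule", "subsystem", "objective_coefficient")

read_cobra_json <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("malformed JSON in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  for (key in c("metabolites", "reactions")) {
    if (is.null(doc[[key]]))
      stop("malformed model file: missing ", sQuote(key), " array", call. = FALSE)
  }
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    if (is.null(m$id)) stop("malformed model file: metabolite without id", call. = FALSE)
    metabolite(id = m$id,
               name = if (is.null(m$name)) m$id else m$name,
               compartment = if (is.null(m$compartment)) "c" else m$compartment,
               formula = if (is.null(m$formula)) NA_character_ else m$formula,
               carbon_count = if (is.null(m$carbon_count)) NA_integer_ else
                 as.integer(m$carbon_count))
  }))
  objective <- NULL
  rxns <- lapply(doc$reactions, function(r) {
    if (is.null(r$id)) stop("malformed model file: reaction without id", call. = FALSE)
    st <- unlist(r$metabolites)
    if (is.null(st)) st <- stats::setNames(numeric(0), character(0))
    if (!is.null(r$objective_coefficient) && r$objective_coefficient != 0)
      objective <<- r$id
    rx <- reaction(id = r$id,
                   stoichiometry = st,
                   lower_bound = if (is.null(r$lower_bound)) -1000 else r$lower_bound,
                   upper_bound = if (is.null(r$upper_bound)) 1000 else r$upper_bound,
                   name = if (is.null(r$name)) r$id else r$name,
                   gpr = if (is.null(r$gene_reaction_rule)) "" else r$gene_reaction_rule,
                   subsystem = if (is.null(r$subsystem)) NA_character_ else r$subsystem)
    extra <- r[setdiff(names(r), KNOWN_RXN_KEYS)]
    if (length(extra)) rx$extra <- extra
    rx
  })
  genes <- if (length(doc$genes)) {
    do.call(rbind, lapply(doc$genes, function(g) {
      prot <- g$protein
      if (is.null(prot) && !is.null(g$annotation$uniprot)) prot <- g$annotation$uniprot
      data.frame(id = g$id,
                 protein = if (is.null(prot)) NA_character_ else prot,
                 mw_kda = if (is.null(g$mw_kda)) NA_real_ else as.numeric(g$mw_kda),
                 stringsAsFactors = FALSE)
    }))
  } else NULL
  if (is.null(objective))
    stop("model file declares no objective (no reaction with nonzero ",
         "objective_coefficient)", call. = FALSE)
  model <- metabolic_model(mets, rxns, genes = genes, objective = objective,
                           validate = FALSE)
  extra_top <- doc[setdiff(names(doc), c("metabolites", "reactions", "genes"))]
  if (length(extra_top)) model$extra <- extra_top
  findings <- validate_model(model)
  if (length(findings))
    stop("invalid model in ", path, ":\n  ",
         paste(findings, collapse = "\n  "), call. = FALSE)
  model
}

write_cobra_json <- function(model, path) {
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    out <- list(id = m$id, name = m$name, compartment = m$compartment)
    if (!is.na(m$formula)) out$formula <- m$formula
    if (!is.na(m$carbon_count)) out$carbon_count <- m$carbon_count
    out
  })
  rxns <- lapply(model$reactions, function(r) {
    out <- list(id = r$id, name = r$name,
                metabolites = as.list(r$stoichiometry),
                lower_bound = r$lower_bound, upper_bound = r$upper_bound,
                gene_reaction_rule = if (is.null(r$gpr)) "" else r$gpr,
                objective_coefficient = if (identical(r$id, model$objective)) 1 else 0)
    if (!is.na(r$subsystem)) out$subsystem <- r$subsystem
    if (!is.null(r$extra)) out <- c(out, r$extra)
    out
  })
  genes <- lapply(seq_len(nrow(model$genes)), function(i) {
    g <- model$genes[i, ]
    out <- list(id = g$id)
    if (!is.na(g$protein)) out$protein <- g$protein
    if (!is.na(g$mw_kda)) out$mw_kda <- g$mw_kda
    out
  })
  doc <- list(metabolites = mets, reactions = unname(rxns), genes = genes)
  if (!is.null(model$extra)) doc <- c(doc, model$extra)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# ---- SBML L3 FBC -----------------------------------------------------------

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

write_sbml <- function(model, path) {
  bnds <- model_bounds(model)
  vals <- sort(unique(c(bnds)))
  pid <- stats::setNames(sprintf("fb_%d", seq_along(vals)), sprintf("%.15g", vals))
  pname <- function(v) pid[[sprintf("%.15g", v)]]

  gpr_xml <- function(node) {
    if (is.character(node))
      return(sprintf('<fbc:geneProductRef fbc:geneProduct="%s"/>', node))
    inner <- paste(vapply(node$args, gpr_xml, character(1)), collapse = "")
    sprintf("<fbc:%s>%s</fbc:%s>", node$op, inner, node$op)
  }

  species <- vapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    extra <- if (!is.na(m$formula))
      sprintf(' fbc:chemicalFormula="%s"', m$formula) else ""
    sprintf(paste0('<species id="%s" name="%s" compartment="%s" constant="false"',
                   ' boundaryCondition="false" hasOnlySubstanceUnits="false"%s/>'),
            m$id, m$name, m$compartment, extra)
  }, character(1))

  comps <- vapply(unique(model$metabolites$compartment), function(cp)
    sprintf('<compartment id="%s" constant="true"/>', cp), character(1))

  params <- vapply(seq_along(vals), function(i)
    sprintf('<parameter id="fb_%d" value="%s" constant="true"/>',
            i, format(vals[i], digits = 15)), character(1))

  rxns <- vapply(model$reactions, function(r) {
    st <- r$stoichiometry
    reac <- st[st < 0]; prod <- st[st > 0]
    lor <- if (length(reac)) paste0("<listOfReactants>",
      paste(sprintf('<speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                    names(reac), format(-unname(reac), digits = 15)), collapse = ""),
      "</listOfReactants>") else ""
    lop <- if (length(prod)) paste0("<listOfProducts>",
      paste(sprintf('<speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                    names(prod), format(unname(prod), digits = 15)), collapse = ""),
      "</listOfProducts>") else ""
    gpa <- ""
    tree <- gpr_parse(r$gpr)
    if (!is.null(tree))
      gpa <- paste0("<fbc:geneProductAssociation>", gpr_xml(tree),
                    "</fbc:geneProductAssociation>")
    sprintf(paste0('<reaction id="%s" name="%s" reversible="%s" fast="false" ',
                   'fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">%s%s%s</reaction>'),
            r$id, r$name, tolower(r$lower_bound < 0),
            pname(r$lower_bound), pname(r$upper_bound), lor, lop, gpa)
  }, character(1))

  gps <- vapply(seq_len(nrow(model$genes)), function(i) {
    g <- model$genes[i, ]
    extra <- if (!is.na(g$protein)) sprintf(' name="%s"', g$protein) else ""
    sprintf('<fbc:geneProduct fbc:id="%s" fbc:label="%s"%s/>', g$id, g$id, extra)
  }, character(1))

  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    sprintf('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" fbc:required="false">',
            SBML_NS, FBC_NS),
    '<model id="model" fbc:strict="true">',
    "<listOfCompartments>", paste(comps, collapse = ""), "</listOfCompartments>",
    "<listOfSpecies>", paste(species, collapse = ""), "</listOfSpecies>",
    "<listOfParameters>", paste(params, collapse = ""), "</listOfParameters>",
    "<listOfReactions>", paste(rxns, collapse = ""), "</listOfReactions>",
    '<fbc:listOfObjectives fbc:activeObjective="obj">',
    '<fbc:objective fbc:id="obj" fbc:type="maximize"><fbc:listOfFluxObjectives>',
    sprintf('<fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>', model$objective),
    "</fbc:listOfFluxObjectives></fbc:objective></fbc:listOfObjectives>",
    "<fbc:listOfGeneProducts>", paste(gps, collapse = ""), "</fbc:listOfGeneProducts>",
    "</model></sbml>")
  writeLines(xml, path)
  invisible(path)
}

read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed SBML in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  ns <- c(s = SBML_NS, fbc = FBC_NS)

  params <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                           xml2::xml_attr(params, "id"))

  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  mets <- do.call(rbind, lapply(sp, function(s) {
    metabolite(id = xml2::xml_attr(s, "id"),
               name = xml2::xml_attr(s, "name"),
               compartment = xml2::xml_attr(s, "compartment"),
               formula = {
                 f <- xml2::xml_attr(s, "chemicalFormula")
                 if (is.na(f)) NA_character_ else f
               })
  }))

  parse_gpa <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") return(xml2::xml_attr(node, "geneProduct"))
    kids <- xml2::xml_children(node)
    list(op = nm, args = lapply(kids, parse_gpa))
  }
  deparse_tree <- function(node, top = TRUE) {
    if (is.character(node)) return(node)
    sep <- paste0(" ", node$op, " ")
    inner <- paste(vapply(node$args, deparse_tree, character(1), top = FALSE),
                   collapse = sep)
    if (top) inner else paste0("(", inner, ")")
  }

  rx_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  rxns <- lapply(rx_nodes, function(rn) {
    id <- xml2::xml_attr(rn, "id")
    get_side <- function(xp, sign) {
      refs <- xml2::xml_find_all(rn, xp, ns)
      stats::setNames(sign * as.numeric(xml2::xml_attr(refs, "stoichiometry")),
                      xml2::xml_attr(refs, "species"))
    }
    st <- c(get_side("./s:listOfReactants/s:speciesReference", -1),
            get_side("./s:listOfProducts/s:speciesReference", +1))
    lbp <- xml2::xml_attr(rn, "lowerFluxBound")
    ubp <- xml2::xml_attr(rn, "upperFluxBound")
    gpa <- xml2::xml_find_first(rn, "./fbc:geneProductAssociation", ns)
    gpr <- ""
    if (!inherits(gpa, "xml_missing")) {
      tree <- parse_gpa(xml2::xml_child(gpa))
      gpr <- deparse_tree(tree)
    }
    reaction(id = id, stoichiometry = st,
             lower_bound = if (is.na(lbp)) -1000 else pvals[[lbp]],
             upper_bound = if (is.na(ubp)) 1000 else pvals[[ubp]],
             name = xml2::xml_attr(rn, "name"), gpr = gpr)
  })

  gp <- xml2::xml_find_all(doc, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  genes <- if (length(gp)) {
    do.call(rbind, lapply(gp, function(g) {
      data.frame(id = xml2::xml_attr(g, "id"),
                 protein = xml2::xml_attr(g, "name"),
                 mw_kda = NA_real_, stringsAsFactors = FALSE)
    }))
  } else NULL

  fo <- xml2::xml_find_first(doc, ".//fbc:fluxObjective", ns)
  if (inherits(fo, "xml_missing"))
    stop("SBML file declares no flux objective", call. = FALSE)
  objective <- xml2::xml_attr(fo, "reaction")

  model <- metabolic_model(mets, rxns, genes = genes, objective = objective,
                           validate = FALSE)
  findings <- validate_model(model)
  if (length(findings))
    stop("invalid model in ", path, ":\n  ",
         paste(findings, collapse = "\n  "), call. = FALSE)
  model
}
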