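#' Read a metabolic model from disk
#'
#' Two dialects are supported.  `json` is the package's documented JSON
#' schema: an object with fields `id`, `compartments`, `metabolites` (array
#' of objects with `id`, `name`, `compartment`, optional `formula`,
#' `annotation`), `reactions` (array of objects with `id`, `name`,
#' `stoichiometry` as a metabolite-id -> coefficient map, `lower_bound`,
#' `upper_bound`, optional `gene_rule`, `subsystem`, `kind`), `genes`, and
#' `objective_reaction_id`.  `sbml` is an SBML Level 3 core subset with flux
#' bounds carried as reaction-local parameters named `LOWER_BOUND` /
#' `UPPER_BOUND` and gene associations, subsystems and reaction kinds in
#' reaction notes (`GENE_ASSOCIATION:`, `SUBSYSTEM:`, `KIND:` lines) — the
#' long-standing constraint-based convention.  Reaction kinds absent from the
#' file are inferred structurally.
#'
#' @param path file to read.
#' @param dialect `"json"` or `"sbml"`; default guesses from the extension.
#' @return a validated `metabolic_model`.
#' @export
read_model <- function(path, dialect = c("auto", "json", "sbml")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml"
               else "json"
  }
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  model <- switch(dialect, json = .read_model_json(path),
                  sbml = .read_model_sbml(path))
  bad <- validate_model(model)
  if (length(bad))
    stop("model in ", path, " failed validation:\n  ",
         paste(bad, collapse = "\n  "), call. = FALSE)
  model
}

.read_model_json <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("JSON parse failure in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  req <- c("id", "compartments", "metabolites", "reactions")
  miss <- setdiff(req, names(doc))
  if (length(miss))
    stop("JSON model ", path, " lacks required field(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  chr1 <- function(x, d = NA_character_) if (is.null(x)) d else as.character(x)
  num1 <- function(x, d = NA_real_) if (is.null(x)) d else as.numeric(x)
  mets <- do.call(rbind, lapply(doc$metabolites, function(m)
    data.frame(id = chr1(m$id), name = chr1(m$name, chr1(m$id)),
               compartment = chr1(m$compartment), formula = chr1(m$formula),
               annotation = chr1(m$annotation), stringsAsFactors = FALSE)))
  rxns <- do.call(rbind, lapply(doc$reactions, function(r)
    data.frame(id = chr1(r$id), name = chr1(r$name, chr1(r$id)),
               lower_bound = num1(r$lower_bound),
               upper_bound = num1(r$upper_bound),
               gene_rule = chr1(r$gene_rule), subsystem = chr1(r$subsystem),
               kind = chr1(r$kind), stringsAsFactors = FALSE)))
  stoich <- setNames(lapply(doc$reactions, function(r) {
    st <- unlist(r$stoichiometry)
    if (is.null(st)) stop("reaction ", r$id, " has no stoichiometry in ", path,
                          call. = FALSE)
    st
  }), vapply(doc$reactions, function(r) chr1(r$id), character(1)))
  metabolic_model(id = chr1(doc$id),
                  compartments = unlist(doc$compartments),
                  metabolites = mets, reactions = rxns, stoichiometry = stoich,
                  genes = unlist(doc$genes),
                  objective_reaction_id = chr1(doc$objective_reaction_id),
                  validate = FALSE)
}

#' Write a metabolic model to disk
#'
#' Writing then re-reading yields an equal model (id-level equality, float
#' bounds within 1e-9) in both dialects; see [read_model()] for the formats.
#'
#' @param model a valid `metabolic_model`.
#' @param path destination file.
#' @param dialect `"json"` or `"sbml"`; default guesses from the extension.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, dialect = c("auto", "json", "sbml")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml"
               else "json"
  }
  assert_valid_model(model)
  switch(dialect, json = .write_model_json(model, path),
         sbml = .write_model_sbml(model, path))
  invisible(path)
}

.write_model_json <- function(model, path) {
  drop_na <- function(x) x[!vapply(x, function(v) is.null(v) ||
                                     (length(v) == 1 && is.na(v)), logical(1))]
  rxns <- lapply(seq_len(nrow(model$reactions)), function(i) {
    r <- model$reactions[i, ]
    drop_na(list(id = r$id, name = r$name,
                 stoichiometry = as.list(model$stoichiometry[[r$id]]),
                 lower_bound = r$lower_bound, upper_bound = r$upper_bound,
                 gene_rule = r$gene_rule, subsystem = r$subsystem,
                 kind = r$kind))
  })
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    drop_na(list(id = m$id, name = m$name, compartment = m$compartment,
                 formula = m$formula, annotation = m$annotation))
  })
  doc <- list(id = model$id,
              compartments = as.list(model$compartments),
              metabolites = mets, reactions = rxns,
              genes = as.list(model$genes))
  if (!is.na(model$objective_reaction_id))
    doc$objective_reaction_id <- model$objective_reaction_id
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

# ---- SBML subset ----------------------------------------------------------

.sbml_ns <- "http://www.sbml.org/sbml/level3/version1/core"
.xhtml_ns <- "http://www.w3.org/1999/xhtml"

.sbml_notes <- function(node) {
  ps <- xml2::xml_find_all(node, ".//*[local-name()='p']")
  out <- list()
  for (p in ps) {
    txt <- xml2::xml_text(p)
    m <- regmatches(txt, regexec("^\\s*([A-Z_]+):\\s*(.*)$", txt))[[1]]
    if (length(m) == 3) out[[m[2]]] <- trimws(m[3])
  }
  out
}

.read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  mdl <- xml2::xml_find_first(doc, ".//*[local-name()='model']")
  if (inherits(mdl, "xml_missing"))
    stop("SBML file ", path, " has no <model> element", call. = FALSE)
  comps <- xml2::xml_attr(
    xml2::xml_find_all(mdl, ".//*[local-name()='compartment']"), "id")
  sp <- xml2::xml_find_all(mdl, ".//*[local-name()='species']")
  mets <- do.call(rbind, lapply(sp, function(s) {
    notes <- .sbml_notes(s)
    data.frame(id = xml2::xml_attr(s, "id"),
               name = xml2::xml_attr(s, "name") %||% xml2::xml_attr(s, "id"),
               compartment = xml2::xml_attr(s, "compartment"),
               formula = notes$FORMULA %||% NA_character_,
               annotation = notes$ANNOTATION %||% NA_character_,
               stringsAsFactors = FALSE)
  }))
  rnodes <- xml2::xml_find_all(mdl, ".//*[local-name()='reaction']")
  stoich <- list(); rows <- list()
  objective <- NA_character_
  mnotes <- .sbml_notes_model(mdl)
  for (rn in rnodes) {
    rid <- xml2::xml_attr(rn, "id")
    st <- numeric()
    for (sr in xml2::xml_find_all(
      rn, ".//*[local-name()='listOfReactants']/*[local-name()='speciesReference']")) {
      st[xml2::xml_attr(sr, "species")] <-
        -as.numeric(xml2::xml_attr(sr, "stoichiometry") %||% "1")
    }
    for (sr in xml2::xml_find_all(
      rn, ".//*[local-name()='listOfProducts']/*[local-name()='speciesReference']")) {
      sid <- xml2::xml_attr(sr, "species")
      st[sid] <- (st[sid] %|0|% 0) +
        as.numeric(xml2::xml_attr(sr, "stoichiometry") %||% "1")
    }
    lps <- xml2::xml_find_all(rn, ".//*[local-name()='localParameter']")
    lb <- NA_real_; ub <- NA_real_
    for (lp in lps) {
      nm <- xml2::xml_attr(lp, "id")
      if (identical(nm, "LOWER_BOUND")) lb <- as.numeric(xml2::xml_attr(lp, "value"))
      if (identical(nm, "UPPER_BOUND")) ub <- as.numeric(xml2::xml_attr(lp, "value"))
    }
    notes <- .sbml_notes(rn)
    if (identical(notes$KIND, "biomass")) objective <- rid
    rows[[rid]] <- data.frame(
      id = rid, name = xml2::xml_attr(rn, "name") %||% rid,
      lower_bound = lb, upper_bound = ub,
      gene_rule = notes$GENE_ASSOCIATION %||% NA_character_,
      subsystem = notes$SUBSYSTEM %||% NA_character_,
      kind = notes$KIND %||% NA_character_, stringsAsFactors = FALSE)
    stoich[[rid]] <- st
  }
  genes <- if (!is.null(mnotes$GENES) && nzchar(mnotes$GENES))
    strsplit(mnotes$GENES, "\\s+")[[1]] else character()
  if (!is.null(mnotes$OBJECTIVE)) objective <- mnotes$OBJECTIVE
  metabolic_model(id = xml2::xml_attr(mdl, "id"), compartments = comps,
                  metabolites = mets, reactions = do.call(rbind, rows),
                  stoichiometry = stoich, genes = genes,
                  objective_reaction_id = objective, validate = FALSE)
}

.sbml_notes_model <- function(mdl) {
  nn <- xml2::xml_find_first(mdl, "./*[local-name()='notes']")
  if (inherits(nn, "xml_missing")) return(list())
  .sbml_notes(nn)
}

.write_notes <- function(parent, fields) {
  fields <- fields[!vapply(fields, function(v) is.null(v) || is.na(v) ||
                             !nzchar(v), logical(1))]
  if (!length(fields)) return(invisible())
  notes <- xml2::xml_add_child(parent, "notes")
  body <- xml2::xml_add_child(notes, "body", xmlns = .xhtml_ns)
  for (nm in names(fields))
    xml2::xml_add_child(body, "p", paste0(nm, ": ", fields[[nm]]))
  invisible()
}

.write_model_sbml <- function(model, path) {
  doc <- xml2::xml_new_root("sbml", xmlns = .sbml_ns, level = "3",
                            version = "1")
  mdl <- xml2::xml_add_child(doc, "model", id = model$id)
  .write_notes(mdl, list(
    GENES = paste(model$genes, collapse = " "),
    OBJECTIVE = if (is.na(model$objective_reaction_id)) NULL
                else model$objective_reaction_id))
  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cp in model$compartments)
    xml2::xml_add_child(lc, "compartment", id = cp, constant = "true")
  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    sn <- xml2::xml_add_child(ls, "species", id = m$id, name = m$name,
                              compartment = m$compartment, constant = "false",
                              boundaryCondition = "false",
                              hasOnlySubstanceUnits = "false")
    .write_notes(sn, list(FORMULA = m$formula, ANNOTATION = m$annotation))
  }
  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    st <- model$stoichiometry[[r$id]]
    rn <- xml2::xml_add_child(lr, "reaction", id = r$id, name = r$name,
                              reversible = tolower(r$lower_bound < 0),
                              fast = "false")
    .write_notes(rn, list(GENE_ASSOCIATION = r$gene_rule,
                          SUBSYSTEM = r$subsystem, KIND = r$kind))
    subs <- st[st < 0]; prods <- st[st > 0]
    if (length(subs)) {
      lrt <- xml2::xml_add_child(rn, "listOfReactants")
      for (s in names(subs))
        xml2::xml_add_child(lrt, "speciesReference", species = s,
                            stoichiometry = format(-subs[[s]], digits = 17),
                            constant = "true")
    }
    if (length(prods)) {
      lpd <- xml2::xml_add_child(rn, "listOfProducts")
      for (s in names(prods))
        xml2::xml_add_child(lpd, "speciesReference", species = s,
                            stoichiometry = format(prods[[s]], digits = 17),
                            constant = "true")
    }
    kl <- xml2::xml_add_child(rn, "kineticLaw")
    lp <- xml2::xml_add_child(kl, "listOfLocalParameters")
    xml2::xml_add_child(lp, "localParameter", id = "LOWER_BOUND",
                        value = format(r$lower_bound, digits = 17))
    xml2::xml_add_child(lp, "localParameter", id = "UPPER_BOUND",
                        value = format(r$upper_bound, digits = 17))
  }
  xml2::write_xml(doc, path)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
`%|0|%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a

# ---- medium TSV -----------------------------------------------------------

#' Read a medium table
#'
#' Expects a TSV with header `metabolite<TAB>max_uptake`, one row per medium
#' component keyed by compartment-free metabolite base id.  Duplicate rows
#' and negative bounds are validation errors; a zero bound keeps the
#' component listed but closed.
#'
#' @param path TSV file.
#' @param name medium label; defaults to the file name.
#' @return a [medium()] object.
#' @export
read_medium <- function(path, name = NULL) {
  if (!file.exists(path)) stop("medium file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, sep = "\t")
  if (!all(c("metabolite", "max_uptake") %in% names(tab)))
    stop("medium table must have columns 'metabolite' and 'max_uptake'",
         call. = FALSE)
  medium(setNames(as.numeric(tab$max_uptake), tab$metabolite),
         name = name %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write a medium table
#'
#' @param x a [medium()] object.
#' @param path destination TSV.
#' @return `path`, invisibly.
#' @export
write_medium <- function(x, path) {
  tab <- data.frame(metabolite = names(x$uptake_bounds),
                    max_uptake = unname(x$uptake_bounds))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
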