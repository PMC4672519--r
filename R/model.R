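#' Construct a metabolic model
#'
#' A `metabolic_model` holds one species' metabolic network: metabolites with
#' compartment assignments, reactions with stoichiometry, flux bounds and
#' optional gene rules, the gene set, and the identifier of the biomass
#' (objective) reaction.  Metabolite identifiers follow the
#' `<base>_<compartment>` convention (e.g. `galactose_e`); the compartment-free
#' base id is the join key used to match shared metabolites across community
#' members.  The extracellular compartment is `"e"` by convention.
#'
#' @param id model identifier (species tag, e.g. `"ST_C106"`).
#' @param compartments character vector of compartment ids (e.g. `c("c","e")`).
#' @param metabolites data frame with columns `id`, `name`, `compartment` and
#'   optionally `formula`, `annotation`.
#' @param reactions data frame with columns `id`, `name`, `lower_bound`,
#'   `upper_bound` and optionally `gene_rule`, `subsystem`, `kind`.  Missing
#'   kinds are inferred (see [infer_reaction_kinds()]); missing bounds default
#'   to `[-1000, 1000]`.
#' @param stoichiometry named list keyed by reaction id; each element a named
#'   numeric vector of signed coefficients keyed by metabolite id (negative =
#'   substrate).
#' @param genes character vector of gene ids.
#' @param objective_reaction_id id of the biomass reaction, or `NA`.
#' @param validate if `TRUE` (default), stop with all diagnostics on any
#'   invariant violation.
#' @return an object of class `metabolic_model`.
#' @seealso [validate_model()], [read_model()], [add_reaction()]
#' @export
metabolic_model <- function(id, compartments, metabolites, reactions,
                            stoichiometry, genes = character(),
                            objective_reaction_id = NA_character_,
                            validate = TRUE) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  for (col in c("formula", "annotation")) {
    if (is.null(metabolites[[col]])) metabolites[[col]] <- NA_character_
  }
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(reactions$name)) reactions$name <- reactions$id
  if (is.null(reactions$gene_rule)) reactions$gene_rule <- NA_character_
  if (is.null(reactions$subsystem)) reactions$subsystem <- NA_character_
  if (is.null(reactions$lower_bound)) reactions$lower_bound <- NA_real_
  if (is.null(reactions$upper_bound)) reactions$upper_bound <- NA_real_

  m <- structure(
    list(id = id,
         compartments = unique(as.character(compartments)),
         metabolites = metabolites,
         reactions = reactions,
         stoichiometry = stoichiometry,
         genes = unique(as.character(genes)),
         objective_reaction_id = objective_reaction_id),
    class = "metabolic_model")
  m <- .default_bounds(m)
  if (is.null(m$reactions$kind) || anyNA(m$reactions$kind)) {
    m <- infer_reaction_kinds(m)
  }
  if (validate) assert_valid_model(m)
  m
}

# reversible reactions default to [-1000, 1000], irreversible to [0, 1000];
# a reaction with no bounds at all is taken as reversible (big-M convention)
.default_bounds <- function(model) {
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  lb[is.na(lb)] <- -1000
  ub[is.na(ub)] <- 1000
  model$reactions$lower_bound <- as.numeric(lb)
  model$reactions$upper_bound <- as.numeric(ub)
  model
}

#' Infer reaction kinds from structure
#'
#' A reaction is classified `biomass` if it is the model objective,
#' `exchange` if it touches exactly one metabolite and that metabolite is
#' extracellular, `transport` if its metabolites span at least two distinct
#' compartments, and `internal` otherwise.  Kinds already present (non-`NA`)
#' are kept.
#'
#' @param model a `metabolic_model`.
#' @param extracellular id of the extracellular compartment.
#' @return the model with a complete `kind` column.
#' @export
infer_reaction_kinds <- function(model, extracellular = "e") {
  comp_of <- setNames(model$metabolites$compartment, model$metabolites$id)
  kind <- model$reactions$kind
  if (is.null(kind)) kind <- rep(NA_character_, nrow(model$reactions))
  for (i in seq_len(nrow(model$reactions))) {
    if (!is.na(kind[i])) next
    rid <- model$reactions$id[i]
    st <- model$stoichiometry[[rid]]
    mets <- names(st)
    comps <- unique(comp_of[mets])
    kind[i] <-
      if (!is.na(model$objective_reaction_id) &&
          identical(rid, model$objective_reaction_id)) "biomass"
      else if (length(mets) == 1L && identical(unname(comps), extracellular)) "exchange"
      else if (length(stats::na.omit(comps)) >= 2L) "transport"
      else "internal"
  }
  model$reactions$kind <- kind
  model
}

#' Validate a metabolic model
#'
#' Checks every structural invariant and returns one diagnostic message per
#' violation (an empty character vector means the model is valid):
#' non-empty unique metabolite and reaction ids, declared compartments,
#' resolvable stoichiometry keys, `lower_bound <= upper_bound`, gene-rule
#' genes present in the gene set, exchange reactions touching exactly one
#' extracellular metabolite, transport reactions spanning at least two
#' compartments, at most one biomass reaction, and a resolvable objective of
#' kind `biomass`.
#'
#' @param model a `metabolic_model`.
#' @param extracellular id of the extracellular compartment.
#' @return character vector of diagnostics, zero-length if valid.
#' @export
validate_model <- function(model, extracellular = "e") {
  bad <- character()
  met <- model$metabolites
  rxn <- model$reactions
  if (any(!nzchar(met$id) | is.na(met$id)))
    bad <- c(bad, "metabolite with empty id")
  if (anyDuplicated(met$id))
    bad <- c(bad, paste0("duplicate metabolite id: ",
                         paste(unique(met$id[duplicated(met$id)]), collapse = ", ")))
  undeclared <- setdiff(unique(met$compartment), model$compartments)
  if (length(undeclared))
    bad <- c(bad, paste0("metabolite compartment not declared: ",
                         paste(undeclared, collapse = ", ")))
  if (anyDuplicated(rxn$id))
    bad <- c(bad, paste0("duplicate reaction id: ",
                         paste(unique(rxn$id[duplicated(rxn$id)]), collapse = ", ")))
  missing_st <- setdiff(rxn$id, names(model$stoichiometry))
  if (length(missing_st))
    bad <- c(bad, paste0("reaction without stoichiometry: ",
                         paste(missing_st, collapse = ", ")))
  comp_of <- setNames(met$compartment, met$id)
  for (i in seq_len(nrow(rxn))) {
    rid <- rxn$id[i]
    st <- model$stoichiometry[[rid]]
    if (is.null(st)) next
    unknown <- setdiff(names(st), met$id)
    if (length(unknown))
      bad <- c(bad, paste0("reaction ", rid, " references unknown metabolite: ",
                           paste(unknown, collapse = ", ")))
    if (rxn$lower_bound[i] > rxn$upper_bound[i])
      bad <- c(bad, paste0("reaction ", rid, ": lower_bound > upper_bound"))
    if (identical(rxn$kind[i], "exchange")) {
      mets <- intersect(names(st), met$id)
      if (length(names(st)) != 1L ||
          !identical(unname(comp_of[mets]), rep(extracellular, length(mets))))
        bad <- c(bad, paste0("exchange reaction ", rid,
                             " must touch exactly one extracellular metabolite"))
    }
    if (identical(rxn$kind[i], "transport")) {
      comps <- unique(stats::na.omit(comp_of[names(st)]))
      if (length(comps) < 2L)
        bad <- c(bad, paste0("transport reaction ", rid,
                             " must span at least two compartments"))
    }
    rule <- rxn$gene_rule[i]
    if (!is.na(rule) && nzchar(rule)) {
      missing_genes <- setdiff(gene_rule_genes(rule), model$genes)
      if (length(missing_genes))
        bad <- c(bad, paste0("reaction ", rid, " gene rule uses undeclared gene: ",
                             paste(missing_genes, collapse = ", ")))
    }
  }
  n_bio <- sum(rxn$kind == "biomass", na.rm = TRUE)
  if (n_bio > 1L) bad <- c(bad, "more than one biomass reaction")
  obj <- model$objective_reaction_id
  if (!is.na(obj)) {
    if (!obj %in% rxn$id)
      bad <- c(bad, paste0("objective_reaction_id does not resolve: ", obj))
    else if (!identical(rxn$kind[rxn$id == obj], "biomass"))
      bad <- c(bad, paste0("objective reaction ", obj, " is not of kind biomass"))
  }
  bad
}

#' @rdname validate_model
#' @export
assert_valid_model <- function(model, extracellular = "e") {
  bad <- validate_model(model, extracellular)
  if (length(bad))
    stop("invalid model '", model$id, "':\n  ",
         paste(bad, collapse = "\n  "), call. = FALSE)
  invisible(model)
}

#' Add a metabolite to a model
#'
#' @param model a `metabolic_model`.
#' @param id metabolite id (`<base>_<compartment>`).
#' @param compartment compartment id.
#' @param name human-readable name.
#' @param formula optional elemental formula.
#' @param annotation optional free-text annotation (e.g. a report compound
#'   name such as `"Folic acid"`).
#' @return the updated model (not revalidated; validate after assembly).
#' @export
add_metabolite <- function(model, id, compartment, name = id,
                           formula = NA_character_,
                           annotation = NA_character_) {
  model$metabolites <- rbind(model$metabolites,
    data.frame(id = id, name = name, compartment = compartment,
               formula = formula, annotation = annotation,
               stringsAsFactors = FALSE))
  model
}

#' Add a reaction to a model
#'
#' @inheritParams add_metabolite
#' @param id reaction id.
#' @param stoichiometry named numeric vector of coefficients (negative =
#'   substrate).
#' @param lower_bound,upper_bound flux bounds (mmol/gDW/h by convention).
#' @param gene_rule optional boolean gene association (`"gA and (gB or gC)"`).
#' @param subsystem optional subsystem label.
#' @param kind one of `internal`, `transport`, `exchange`, `biomass`, or `NA`
#'   to infer later.
#' @param name human-readable reaction name.
#' @return the updated model.
#' @export
add_reaction <- function(model, id, stoichiometry, lower_bound = 0,
                         upper_bound = 1000, gene_rule = NA_character_,
                         subsystem = NA_character_, kind = NA_character_,
                         name = id) {
  model$reactions <- rbind(model$reactions,
    data.frame(id = id, name = name, lower_bound = lower_bound,
               upper_bound = upper_bound, gene_rule = gene_rule,
               subsystem = subsystem, kind = kind, stringsAsFactors = FALSE))
  model$stoichiometry[[id]] <- stoichiometry
  model
}

# empty shell used by builders (synthetic fixtures, reconstruction)
.empty_model <- function(id, compartments = c("c", "e")) {
  structure(
    list(id = id, compartments = compartments,
         metabolites = data.frame(id = character(), name = character(),
                                  compartment = character(),
                                  formula = character(),
                                  annotation = character(),
                                  stringsAsFactors = FALSE),
         reactions = data.frame(id = character(), name = character(),
                                lower_bound = numeric(),
                                upper_bound = numeric(),
                                gene_rule = character(),
                                subsystem = character(), kind = character(),
                                stringsAsFactors = FALSE),
         stoichiometry = list(),
         genes = character(),
         objective_reaction_id = NA_character_),
    class = "metabolic_model")
}

#' Compartment-free base id of a metabolite
#'
#' Strips the trailing `_<compartment>` suffix, e.g. `galactose_e` ->
#' `galactose`.
#'
#' @param met_id metabolite id(s).
#' @param compartment the compartment suffix to strip.
#' @return character vector of base ids.
#' @export
met_base_id <- function(met_id, compartment) {
  sub(paste0("_", compartment, "$"), "", met_id)
}

#' Test two models for id-level equality
#'
#' Models are equal when they contain the same metabolites, reactions
#' (bounds within `tol`), stoichiometries (within `tol`), genes, compartments
#' and objective, irrespective of row order.
#'
#' @param a,b `metabolic_model` objects.
#' @param tol numeric tolerance on bounds and coefficients.
#' @return `TRUE` or `FALSE`.
#' @export
models_equal <- function(a, b, tol = 1e-9) {
  if (!identical(a$id, b$id)) return(FALSE)
  if (!setequal(a$compartments, b$compartments)) return(FALSE)
  if (!setequal(a$genes, b$genes)) return(FALSE)
  if (!identical(is.na(a$objective_reaction_id), is.na(b$objective_reaction_id)))
    return(FALSE)
  if (!is.na(a$objective_reaction_id) &&
      !identical(a$objective_reaction_id, b$objective_reaction_id)) return(FALSE)
  ma <- a$metabolites[order(a$metabolites$id), , drop = FALSE]
  mb <- b$metabolites[order(b$metabolites$id), , drop = FALSE]
  if (!identical(ma$id, mb$id)) return(FALSE)
  same_chr <- function(x, y) all((is.na(x) & is.na(y)) | (!is.na(x) & !is.na(y) & x == y))
  for (col in c("name", "compartment", "formula", "annotation"))
    if (!same_chr(ma[[col]], mb[[col]])) return(FALSE)
  ra <- a$reactions[order(a$reactions$id), , drop = FALSE]
  rb <- b$reactions[order(b$reactions$id), , drop = FALSE]
  if (!identical(ra$id, rb$id)) return(FALSE)
  for (col in c("name", "gene_rule", "subsystem", "kind"))
    if (!same_chr(ra[[col]], rb[[col]])) return(FALSE)
  if (max(abs(ra$lower_bound - rb$lower_bound),
          abs(ra$upper_bound - rb$upper_bound)) > tol) return(FALSE)
  for (rid in ra$id) {
    sa <- a$stoichiometry[[rid]]; sb <- b$stoichiometry[[rid]]
    if (!setequal(names(sa), names(sb))) return(FALSE)
    if (max(abs(sa[names(sa)] - sb[names(sa)])) > tol) return(FALSE)
  }
  TRUE
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n",
      "  compartments: ", paste(x$compartments, collapse = ", "), "\n",
      "  metabolites:  ", nrow(x$metabolites), "\n",
      "  reactions:    ", nrow(x$reactions), " (",
      paste(names(table(x$reactions$kind)), table(x$reactions$kind),
            sep = ":", collapse = ", "), ")\n",
      "  genes:        ", length(x$genes), "\n",
      "  objective:    ", x$objective_reaction_id, "\n", sep = "")
  invisible(x)
}

#' Construct a growth medium
#'
#' A medium is a table of maximum uptake rates for extracellular metabolites,
#' keyed by compartment-free base id.  When a system is built against a
#' medium, the exchange lower bound of each listed metabolite is opened to
#' `-max_uptake`; extracellular metabolites absent from the medium cannot be
#' taken up (secretion stays open).
#'
#' @param uptake_bounds named nonnegative numeric vector, names are
#'   metabolite base ids.
#' @param name medium label.
#' @return object of class `medium`.
#' @export
medium <- function(uptake_bounds, name = "medium") {
  uptake_bounds <- unlist(uptake_bounds)
  if (length(uptake_bounds) && is.null(names(uptake_bounds)))
    stop("uptake_bounds must be named by metabolite base id")
  if (anyDuplicated(names(uptake_bounds)))
    stop("duplicate metabolite in medium: ",
         paste(unique(names(uptake_bounds)[duplicated(names(uptake_bounds))]),
               collapse = ", "))
  if (any(uptake_bounds < 0))
    stop("negative uptake bound for: ",
         paste(names(uptake_bounds)[uptake_bounds < 0], collapse = ", "))
  structure(list(name = name,
                 uptake_bounds = uptake_bounds[order(names(uptake_bounds))]),
            class = "medium")
}

#' @export
print.medium <- function(x, ...) {
  cat("<medium> ", x$name, " (", length(x$uptake_bounds), " components)\n",
      sep = "")
  if (length(x$uptake_bounds)) print(x$uptake_bounds)
  invisible(x)
}
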