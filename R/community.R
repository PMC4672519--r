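#' Merge two member models into a balanced-growth community model
#'
#' Internal (non-extracellular) metabolites, all member reactions and all
#' genes are prefixed with the member tag (`<tag>__`); extracellular
#' metabolites are merged on their compartment-free base id into a single
#' shared compartment.  Member exchange reactions are replaced by exactly one
#' community exchange reaction per extracellular metabolite (`EX_<base>_e`),
#' with medium bounds applied; member transport reactions are preserved.  One
#' extra constraint row enforces balanced growth, `v_bioA - v_bioB = 0`, the
#' steady-state requirement for a consortium of constant composition.  The
#' community objective is member A's biomass flux (equal to B's under the
#' coupling).
#'
#' @param model_A,model_B valid `metabolic_model`s, each with a biomass
#'   objective and an extracellular compartment.
#' @param medium a [medium()] applied to the community exchanges.
#' @param extracellular id of the shared extracellular compartment.
#' @return an object of class `community_model`: list with `members`
#'   (named list of the two input models), `tags`, `system` (the coupled
#'   `stoich_system`), `shared_metabolites` (data frame `base_id`, `donor`,
#'   `recipient`), `biomass_cols`, and `medium`.
#' @export
build_community <- function(model_A, model_B, medium,
                            extracellular = "e") {
  assert_valid_model(model_A, extracellular)
  assert_valid_model(model_B, extracellular)
  for (m in list(model_A, model_B)) {
    if (!extracellular %in% m$compartments)
      stop("member '", m$id, "' declares no extracellular compartment",
           call. = FALSE)
    if (is.na(m$objective_reaction_id))
      stop("member '", m$id, "' has no biomass objective", call. = FALSE)
  }
  tags <- c(model_A$id, model_B$id)
  if (tags[1] == tags[2])
    stop("member models must have distinct ids", call. = FALSE)

  pieces <- Map(.namespace_member, list(model_A, model_B), tags,
                MoreArgs = list(extracellular = extracellular))
  ex_mets <- sort(unique(c(pieces[[1]]$ex_mets, pieces[[2]]$ex_mets)))

  met_ids <- c(pieces[[1]]$met_ids, pieces[[2]]$met_ids, ex_mets)
  rxn_all <- c(pieces[[1]]$rxns, pieces[[2]]$rxns)
  ex_rxn_ids <- paste0("EX_", ex_mets)
  col_ids <- c(names(rxn_all), ex_rxn_ids)

  S <- matrix(0, length(met_ids), length(col_ids),
              dimnames = list(met_ids, col_ids))
  lb <- setNames(numeric(length(col_ids)), col_ids)
  ub <- setNames(numeric(length(col_ids)), col_ids)
  for (rid in names(rxn_all)) {
    r <- rxn_all[[rid]]
    S[names(r$st), rid] <- r$st
    lb[rid] <- r$lb; ub[rid] <- r$ub
  }
  bases <- met_base_id(ex_mets, extracellular)
  for (i in seq_along(ex_mets)) {
    S[ex_mets[i], ex_rxn_ids[i]] <- -1
    lb[ex_rxn_ids[i]] <- if (bases[i] %in% names(medium$uptake_bounds))
      -medium$uptake_bounds[[bases[i]]] else 0
    ub[ex_rxn_ids[i]] <- 1000
  }
  orphan <- setdiff(names(medium$uptake_bounds), bases)
  if (length(orphan))
    warning("medium component(s) with no community exchange: ",
            paste(orphan, collapse = ", "), call. = FALSE)

  bio <- paste0(tags, "__",
                c(model_A$objective_reaction_id, model_B$objective_reaction_id))
  coupling <- setNames(numeric(length(col_ids)), col_ids)
  coupling[bio] <- c(1, -1)
  S <- rbind(S, coupling = coupling)
  obj <- setNames(numeric(length(col_ids)), col_ids)
  obj[bio[1]] <- 1

  system <- structure(
    list(S = S, lb = lb, ub = ub, obj = obj,
         b = setNames(numeric(nrow(S)), rownames(S)),
         row_ids = rownames(S), col_ids = col_ids),
    class = "stoich_system")

  comm <- structure(
    list(members = setNames(list(model_A, model_B), tags), tags = tags,
         system = system, biomass_cols = setNames(bio, tags),
         medium = medium, extracellular = extracellular),
    class = "community_model")
  comm$shared_metabolites <- list_shared_metabolites(comm)
  comm
}

# prefix one member's namespace; drop its exchange reactions
.namespace_member <- function(model, tag, extracellular) {
  is_ex_met <- model$metabolites$compartment == extracellular
  met_map <- ifelse(is_ex_met, model$metabolites$id,
                    paste0(tag, "__", model$metabolites$id))
  names(met_map) <- model$metabolites$id
  keep <- model$reactions$kind != "exchange"
  rxns <- list()
  for (i in which(keep)) {
    rid <- model$reactions$id[i]
    st <- model$stoichiometry[[rid]]
    names(st) <- met_map[names(st)]
    rxns[[paste0(tag, "__", rid)]] <-
      list(st = st, lb = model$reactions$lower_bound[i],
           ub = model$reactions$upper_bound[i])
  }
  list(met_ids = unname(met_map[!is_ex_met]),
       ex_mets = unname(met_map[is_ex_met]),
       rxns = rxns)
}

#' @export
print.community_model <- function(x, ...) {
  cat("<community_model> ", paste(x$tags, collapse = " + "), "\n",
      "  system: ", length(x$system$row_ids), " rows x ",
      length(x$system$col_ids), " reactions (incl. coupling row)\n",
      "  shared metabolites: ",
      paste(unique(x$shared_metabolites$base_id), collapse = ", "), "\n",
      "  medium: ", x$medium$name, "\n", sep = "")
  invisible(x)
}

#' Mono-culture growth rate
#'
#' FBA optimum of a single member on a medium — e.g. to confirm that a
#' proteolysis- and lactose-negative strain cannot grow in milk alone while
#' its partner can.
#'
#' @param model a valid `metabolic_model`.
#' @param medium a [medium()].
#' @return the optimal growth rate (0 if the optimum is zero; `NA` if the
#'   LP is not optimal).
#' @export
mono_growth <- function(model, medium) {
  sol <- solve_fba(build_system(model, medium))
  if (sol$status != "optimal") return(NA_real_)
  sol$objective_value
}

#' List shared (cross-feedable) metabolites of a community
#'
#' An extracellular metabolite is shared when one member can secrete it and
#' the other can take it up.  The uptake (recipient) side must be a transport
#' reaction able to consume the extracellular species under its bounds.  The
#' secretion (donor) side is any member reaction able to produce the
#' extracellular species — a transport, or a member-owned extracellular
#' enzyme such as a cell-wall protease releasing peptides.  Community
#' exchange pseudo-reactions are never considered.
#'
#' @param community a `community_model`.
#' @return data frame with one row per candidate direction: `base_id`,
#'   `donor`, `recipient`, sorted by `base_id` then donor.
#' @export
list_shared_metabolites <- function(community) {
  ex <- community$extracellular
  tags <- community$tags
  can_produce <- list(); can_consume <- list()
  for (tag in tags) {
    model <- community$members[[tag]]
    comp_of <- setNames(model$metabolites$compartment, model$metabolites$id)
    prod <- character(); cons <- character()
    for (i in seq_len(nrow(model$reactions))) {
      r <- model$reactions[i, ]
      if (r$kind == "exchange") next
      st <- model$stoichiometry[[r$id]]
      emets <- names(st)[comp_of[names(st)] == ex]
      for (mid in emets) {
        co <- st[[mid]]
        if ((co > 0 && r$upper_bound > 0) || (co < 0 && r$lower_bound < 0))
          prod <- c(prod, mid)
        if (r$kind == "transport" &&
            ((co < 0 && r$upper_bound > 0) || (co > 0 && r$lower_bound < 0)))
          cons <- c(cons, mid)
      }
    }
    can_produce[[tag]] <- unique(met_base_id(prod, ex))
    can_consume[[tag]] <- unique(met_base_id(cons, ex))
  }
  rows <- list()
  for (donor in tags) for (recipient in setdiff(tags, donor)) {
    both <- intersect(can_produce[[donor]], can_consume[[recipient]])
    for (b in both)
      rows[[length(rows) + 1L]] <- data.frame(
        base_id = b, donor = donor, recipient = recipient,
        stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(base_id = character(), donor = character(),
                         recipient = character(), stringsAsFactors = FALSE)
  out <- out[order(out$base_id, match(out$donor, tags)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# transport reactions (community column ids) of `tag` able to consume the
# extracellular metabolite `base`; used by the knockout screen
.recipient_transports <- function(community, base, tag) {
  model <- community$members[[tag]]
  ex <- community$extracellular
  comp_of <- setNames(model$metabolites$compartment, model$metabolites$id)
  mid <- paste0(base, "_", ex)
  hits <- character()
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    if (r$kind != "transport") next
    st <- model$stoichiometry[[r$id]]
    if (!mid %in% names(st)) next
    co <- st[[mid]]
    if ((co < 0 && r$upper_bound > 0) || (co > 0 && r$lower_bound < 0))
      hits <- c(hits, paste0(tag, "__", r$id))
  }
  hits
}

# all transports of `tag` touching the metabolite (either direction)
.member_transports <- function(community, base, tag) {
  model <- community$members[[tag]]
  ex <- community$extracellular
  mid <- paste0(base, "_", ex)
  sel <- vapply(model$reactions$id, function(rid)
    mid %in% names(model$stoichiometry[[rid]]) &&
      model$reactions$kind[model$reactions$id == rid] == "transport",
    logical(1))
  paste0(tag, "__", model$reactions$id[sel])
}
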