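#' Read a protein set from FASTA
#'
#' @param path amino-acid FASTA; record ids (first whitespace-delimited
#'   token) become gene ids.
#' @return named character vector of uppercase sequences.
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(aa))
  names(seqs) <- sub("\\s.*$", "", names(aa))
  .check_protein_set(seqs)
  seqs
}

.check_protein_set <- function(seqs) {
  if (any(!nzchar(seqs)))
    stop("empty protein sequence for: ",
         paste(names(seqs)[!nzchar(seqs)], collapse = ", "), call. = FALSE)
  invisible(seqs)
}

.kmer_set <- function(seq, k) {
  if (nchar(seq) < k) return(character())
  unique(substring(seq, seq_len(nchar(seq) - k + 1L),
                   k:nchar(seq)))
}

#' Orthology by k-mer Jaccard bidirectional best hit
#'
#' Similarity between two protein sequences is the Jaccard index of their
#' k-mer sets.  A `(query, reference)` pair is reported iff each sequence is
#' the other's unique best match and the similarity reaches `min_score`.
#' Deterministic, alignment-free, and adequate at desk scale; externally
#' computed ortholog tables can be supplied instead via
#' [read_ortholog_table()].
#'
#' @param query,reference named character vectors of amino-acid sequences
#'   (gene id -> sequence).
#' @param k k-mer length (>= 3).
#' @param min_score minimum Jaccard similarity in `[0, 1]`.
#' @return data frame (`query_gene`, `reference_gene`, `score`) sorted by
#'   descending score, ties broken lexicographically by `query_gene`.
#' @export
kmer_bbh <- function(query, reference, k = 5, min_score = 0.3) {
  stopifnot(k >= 3, min_score >= 0, min_score <= 1)
  .check_protein_set(query); .check_protein_set(reference)
  qk <- lapply(query, .kmer_set, k = k)
  rk <- lapply(reference, .kmer_set, k = k)
  sim <- matrix(0, length(query), length(reference),
                dimnames = list(names(query), names(reference)))
  for (i in seq_along(qk)) {
    for (j in seq_along(rk)) {
      un <- length(union(qk[[i]], rk[[j]]))
      sim[i, j] <- if (un == 0) 0 else
        length(intersect(qk[[i]], rk[[j]])) / un
    }
  }
  pairs <- list()
  for (i in seq_along(qk)) {
    s <- sim[i, ]
    best <- max(s)
    if (best < min_score) next
    if (sum(s == best) != 1L) next          # not a unique best hit
    j <- which(s == best)
    back <- sim[, j]
    if (sum(back == max(back)) != 1L || which.max(back) != i) next
    pairs[[length(pairs) + 1L]] <-
      data.frame(query_gene = names(query)[i],
                 reference_gene = names(reference)[j],
                 score = best, stringsAsFactors = FALSE)
  }
  out <- if (length(pairs)) do.call(rbind, pairs)
         else data.frame(query_gene = character(),
                         reference_gene = character(), score = numeric(),
                         stringsAsFactors = FALSE)
  out[order(-out$score, out$query_gene), , drop = FALSE]
}

#' Read / write an ortholog pair table
#'
#' TSV with header `query<TAB>reference<TAB>score`; scores must lie in
#' `[0, 1]` and `(query, reference)` pairs must be unique.
#'
#' @param path TSV file.
#' @return data frame (`query_gene`, `reference_gene`, `score`).
#' @export
read_ortholog_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("query", "reference", "score") %in% names(tab)))
    stop("ortholog table needs columns query, reference, score", call. = FALSE)
  out <- data.frame(query_gene = tab$query, reference_gene = tab$reference,
                    score = as.numeric(tab$score), stringsAsFactors = FALSE)
  .check_pairs(out)
  out
}

#' @rdname read_ortholog_table
#' @param pairs data frame as returned by [kmer_bbh()].
#' @export
write_ortholog_table <- function(pairs, path) {
  tab <- data.frame(query = pairs$query_gene, reference = pairs$reference_gene,
                    score = pairs$score)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.check_pairs <- function(pairs) {
  if (any(pairs$score < 0 | pairs$score > 1))
    stop("ortholog scores must lie in [0, 1]", call. = FALSE)
  if (anyDuplicated(pairs[c("query_gene", "reference_gene")]))
    stop("duplicate (query, reference) ortholog pair", call. = FALSE)
  invisible(pairs)
}

#' Transfer gene-associated reactions via an ortholog map
#'
#' Builds a draft model for a query organism from a reference model: a
#' gene-associated reference reaction is kept iff its gene rule evaluates
#' `TRUE` when mapped reference genes are set present and unmapped genes
#' absent (conservative transfer).  Mapped gene ids in kept rules are
#' rewritten to the query's gene ids; reference ids left in a rule by partial
#' mapping are retained and added to the draft's gene set so the provenance
#' of unsupported rule branches stays visible.  Metabolites referenced by
#' kept reactions are carried over, and the biomass reaction is always
#' carried (growth is not orthology-transferable).  Non-gene-associated
#' reactions are added separately by [add_non_gene_reactions()].
#'
#' @param reference_model a valid `metabolic_model`.
#' @param pairs ortholog pairs (`query_gene`, `reference_gene`, `score`).
#' @param query_id id for the draft model.
#' @return a draft `metabolic_model`.
#' @export
transfer_reactions <- function(reference_model, pairs, query_id) {
  assert_valid_model(reference_model)
  .check_pairs(pairs)
  unknown <- setdiff(pairs$reference_gene, reference_model$genes)
  if (length(unknown))
    stop("ortholog pair references unknown reference gene(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  map <- setNames(pairs$query_gene, pairs$reference_gene)
  mapped_ref <- names(map)
  keep <- logical(nrow(reference_model$reactions))
  for (i in seq_len(nrow(reference_model$reactions))) {
    r <- reference_model$reactions[i, ]
    if (identical(r$kind, "biomass")) { keep[i] <- TRUE; next }
    verdict <- eval_gene_rule(r$gene_rule, mapped_ref)
    keep[i] <- isTRUE(verdict)
  }
  draft <- .subset_model(reference_model, reference_model$reactions$id[keep])
  draft$id <- query_id
  # rewrite rules to query gene ids
  draft$reactions$gene_rule <- vapply(draft$reactions$gene_rule, .gr_rewrite,
                                      character(1), map = map,
                                      USE.NAMES = FALSE)
  draft$genes <- sort(unique(unlist(
    lapply(draft$reactions$gene_rule, gene_rule_genes))))
  assert_valid_model(draft)
  draft
}

# reaction-id subset of a model, carrying only referenced metabolites
.subset_model <- function(model, rxn_ids) {
  keep <- model$reactions$id %in% rxn_ids
  rxns <- model$reactions[keep, , drop = FALSE]
  stoich <- model$stoichiometry[rxns$id]
  mets_used <- unique(unlist(lapply(stoich, names)))
  mets <- model$metabolites[model$metabolites$id %in% mets_used, , drop = FALSE]
  obj <- model$objective_reaction_id
  if (!is.na(obj) && !obj %in% rxns$id) obj <- NA_character_
  structure(list(id = model$id, compartments = model$compartments,
                 metabolites = mets, reactions = rxns, stoichiometry = stoich,
                 genes = model$genes, objective_reaction_id = obj),
            class = "metabolic_model")
}

#' Add non-gene-associated reactions from a reference
#'
#' Copies every reference reaction that has no gene rule (exchanges,
#' spontaneous transports, and other non-gene-associated steps) into the
#' draft, deduplicating by reaction id.  Idempotent.  An id collision with
#' differing stoichiometry or bounds is a conflict error.
#'
#' @param draft the draft `metabolic_model`.
#' @param reference_model the reference to copy from.
#' @return the augmented draft.
#' @export
add_non_gene_reactions <- function(draft, reference_model) {
  no_gene <- is.na(reference_model$reactions$gene_rule) |
    !nzchar(trimws(reference_model$reactions$gene_rule))
  .copy_reactions(draft, reference_model,
                  reference_model$reactions$id[no_gene])
}

#' Copy whole subsystems from a reference
#'
#' Copies all reference reactions whose `subsystem` is listed, verbatim
#' (gene rules included; genes used by the copied rules are added to the
#' draft's gene set), deduplicated by id.  Intended for pathway details such
#' as cell wall components or fatty acid biosynthesis that are carried over
#' from reference models rather than re-derived by orthology.
#'
#' @param draft the draft `metabolic_model`.
#' @param reference_model the reference to copy from.
#' @param subsystems character vector of subsystem names; every name must
#'   exist in the reference.
#' @return the augmented draft.
#' @export
copy_subsystems <- function(draft, reference_model, subsystems) {
  known <- unique(stats::na.omit(reference_model$reactions$subsystem))
  unknown <- setdiff(subsystems, known)
  if (length(unknown))
    stop("unknown subsystem(s): ", paste(unknown, collapse = ", "),
         "; known: ", paste(known, collapse = ", "), call. = FALSE)
  sel <- !is.na(reference_model$reactions$subsystem) &
    reference_model$reactions$subsystem %in% subsystems
  .copy_reactions(draft, reference_model, reference_model$reactions$id[sel])
}

.copy_reactions <- function(draft, reference_model, rxn_ids) {
  for (rid in rxn_ids) {
    ref_st <- reference_model$stoichiometry[[rid]]
    i <- match(rid, reference_model$reactions$id)
    r <- reference_model$reactions[i, , drop = FALSE]
    if (rid %in% draft$reactions$id) {
      cur <- draft$stoichiometry[[rid]]
      same <- setequal(names(cur), names(ref_st)) &&
        max(abs(cur[names(cur)] - ref_st[names(cur)])) <= 1e-9
      if (!same)
        stop("reaction id collision with differing stoichiometry: ", rid,
             call. = FALSE)
      next
    }
    draft$reactions <- rbind(draft$reactions, r)
    draft$stoichiometry[[rid]] <- ref_st
    new_mets <- setdiff(names(ref_st), draft$metabolites$id)
    if (length(new_mets)) {
      draft$metabolites <- rbind(
        draft$metabolites,
        reference_model$metabolites[
          match(new_mets, reference_model$metabolites$id), , drop = FALSE])
    }
    draft$genes <- union(draft$genes, gene_rule_genes(r$gene_rule))
  }
  draft$compartments <- union(draft$compartments,
                              unique(draft$metabolites$compartment))
  if (is.na(draft$objective_reaction_id)) {
    bio <- draft$reactions$id[draft$reactions$kind == "biomass"]
    if (length(bio) == 1L) draft$objective_reaction_id <- bio
  }
  assert_valid_model(draft)
  draft
}
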