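GROWTH_TOL <- 1e-6   # growth below this counts as abolished

#' Screen cross-feeding interactions by transport knockouts
#'
#' For every shared metabolite and candidate direction (donor -> recipient):
#' record the transfer flux through the recipient's uptake transports at the
#' community pFBA optimum; knock out all of the recipient's transport
#' reactions for the metabolite (by default — `side = "donor"` disables the
#' donor's transports instead, for sensitivity analysis), re-solve the FBA,
#' and mark the transfer `essential` iff growth falls below 1e-6; and mark
#' the direction `robust` iff the flux variability interval of the
#' recipient's net uptake at `fraction` of the optimum does not straddle
#' zero.  Records with zero transfer flux that are not essential are
#' retained but flagged inactive.
#'
#' @param community a `community_model` whose baseline FBA is optimal with
#'   growth above 1e-6.
#' @param side which member's transports to disable per knockout.
#' @param fraction fraction of the optimum maintained in the robustness FVA.
#' @return an object of class `screen_report`: list with `records` (one data
#'   frame row per candidate direction), `baseline_growth`, `mono_growth_A`,
#'   `mono_growth_B`, and `groups_tested` (filled by [screen_groups()]).
#' @export
screen_interactions <- function(community, side = c("recipient", "donor"),
                                fraction = 0.999) {
  side <- match.arg(side)
  sys <- community$system
  base <- solve_fba(sys)
  if (base$status != "optimal" || base$objective_value < GROWTH_TOL)
    stop("community baseline must be optimal with growth > 1e-6 (got ",
         base$status, ", ", format(base$objective_value), ")", call. = FALSE)
  pf <- solve_pfba(sys)
  shared <- community$shared_metabolites
  n <- nrow(shared)
  rec <- data.frame(metabolite = character(n), compound_name = character(n),
                    donor = character(n), recipient = character(n),
                    transfer_flux = numeric(n), essential = logical(n),
                    growth_after_knockout = numeric(n),
                    direction_robust = logical(n), active = logical(n),
                    redundancy_group = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    b <- shared$base_id[i]; donor <- shared$donor[i]
    recipient <- shared$recipient[i]
    uptake_cols <- .recipient_transports(community, b, recipient)
    w <- .uptake_weights(community, b, recipient, uptake_cols)
    flux <- sum(w * pf$fluxes[uptake_cols])
    ko_tag <- if (side == "recipient") recipient else donor
    ko_cols <- .member_transports(community, b, ko_tag)
    after <- solve_fba(knockout(sys, ko_cols))
    g <- if (after$status == "optimal") after$objective_value else 0
    wfull <- setNames(numeric(length(sys$col_ids)), sys$col_ids)
    wfull[uptake_cols] <- w
    lo <- .opt_functional(sys, unname(wfull), fraction, base$objective_value,
                          FALSE)
    hi <- .opt_functional(sys, unname(wfull), fraction, base$objective_value,
                          TRUE)
    rec$metabolite[i] <- b
    rec$compound_name[i] <- .compound_name(community, b)
    rec$donor[i] <- donor
    rec$recipient[i] <- recipient
    rec$transfer_flux[i] <- flux
    rec$essential[i] <- g < GROWTH_TOL
    rec$growth_after_knockout[i] <- g
    rec$direction_robust[i] <- !(lo < -GROWTH_TOL && hi > GROWTH_TOL)
    rec$active[i] <- flux > GROWTH_TOL || g < GROWTH_TOL
  }
  monos <- vapply(community$members, mono_growth, numeric(1),
                  medium = community$medium)
  structure(list(records = rec, baseline_growth = base$objective_value,
                 mono_growth_A = unname(monos[1]),
                 mono_growth_B = unname(monos[2]),
                 pfba_fluxes = pf$fluxes,
                 side = side, groups_tested = NULL,
                 solver = .solver_info()),
            class = "screen_report")
}

# +1 weight per unit of net uptake for each recipient transport column
.uptake_weights <- function(community, base, tag, cols) {
  model <- community$members[[tag]]
  mid <- paste0(base, "_", community$extracellular)
  vapply(cols, function(col) {
    rid <- sub(paste0("^", tag, "__"), "", col)
    -model$stoichiometry[[rid]][[mid]]
  }, numeric(1))
}

.compound_name <- function(community, base) {
  ex <- community$extracellular
  mid <- paste0(base, "_", ex)
  for (model in community$members) {
    j <- match(mid, model$metabolites$id)
    if (!is.na(j)) {
      ann <- model$metabolites$annotation[j]
      if (!is.na(ann) && nzchar(ann)) return(ann)
      nm <- model$metabolites$name[j]
      if (!is.na(nm) && nzchar(nm)) return(nm)
    }
  }
  base
}

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen_report> baseline growth ", format(x$baseline_growth),
      "; mono A ", format(x$mono_growth_A), ", mono B ",
      format(x$mono_growth_B), "\n", sep = "")
  print(x$records[x$records$active,
                  c("metabolite", "donor", "recipient", "transfer_flux",
                    "essential", "direction_robust")])
  invisible(x)
}

#' Joint knockouts of metabolite groups
#'
#' Knocks out, for each group, the recipient-side transports of every
#' metabolite in the group simultaneously and re-solves.  A group is jointly
#' essential iff growth falls below 1e-6 while every singleton knockout
#' inside it leaves growth at or above 1e-6 — the signature of a redundancy
#' (OR) group such as interchangeable purine sources or carbon sources.
#'
#' @param community a `community_model`.
#' @param groups list of character vectors of shared metabolite base ids.
#' @return data frame with `group` (metabolites joined by `+`), `growth`,
#'   `jointly_essential`.
#' @export
screen_groups <- function(community, groups) {
  shared <- unique(community$shared_metabolites$base_id)
  sys <- community$system
  base <- solve_fba(sys)
  single_growth <- vapply(shared, function(b)
    .joint_knockout_growth(community, b), numeric(1))
  out <- data.frame(group = character(), growth = numeric(),
                    jointly_essential = logical(), stringsAsFactors = FALSE)
  for (g in groups) {
    unknown <- setdiff(g, shared)
    if (length(unknown))
      stop("not a shared metabolite: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    growth <- if (length(g)) .joint_knockout_growth(community, g)
              else base$objective_value
    jointly <- length(g) > 0 && growth < GROWTH_TOL &&
      all(single_growth[g] >= GROWTH_TOL)
    out <- rbind(out, data.frame(
      group = paste(sort(g), collapse = "+"), growth = growth,
      jointly_essential = jointly, stringsAsFactors = FALSE))
  }
  out
}

.joint_knockout_growth <- function(community, bases) {
  cols <- character()
  shared <- community$shared_metabolites
  for (b in bases) {
    recips <- unique(shared$recipient[shared$base_id == b])
    for (tag in recips)
      cols <- c(cols, .member_transports(community, b, tag))
  }
  sol <- solve_fba(knockout(community$system, unique(cols)))
  if (sol$status != "optimal") 0 else sol$objective_value
}

#' Discover minimal jointly-essential metabolite groups
#'
#' Enumerates subsets (size 2 up to `max_size`, lexicographic order) of the
#' individually non-essential shared metabolites and returns the minimal
#' jointly-essential sets.  Metabolites are eligible whenever a transfer
#' route exists, regardless of their flux at the reference optimum: a member
#' of a redundancy group can carry zero flux in one particular optimal flux
#' distribution while still being one of the interchangeable suppliers.
#' Supersets of an already-found essential set are skipped, so only minimal
#' groups are reported.
#'
#' @param community a `community_model`.
#' @param max_size largest group size to enumerate.
#' @return list of character vectors (each sorted), ordered by size then
#'   lexicographically; empty when every transfer is individually essential
#'   or no redundancy exists.
#' @export
auto_groups <- function(community, max_size = 3) {
  shared <- sort(unique(community$shared_metabolites$base_id))
  single <- vapply(shared, function(b)
    .joint_knockout_growth(community, b), numeric(1))
  pool <- shared[single >= GROWTH_TOL]
  n <- length(pool)
  if (n < 2) return(list())
  total <- sum(vapply(2:min(max_size, n), function(k)
    choose(n, k), numeric(1)))
  if (total > 2^15)
    stop("auto_groups: ", total, " candidate subsets exceed the enumeration ",
         "cap (2^15); pass explicit groups to screen_groups()", call. = FALSE)
  found <- list()
  for (k in 2:min(max_size, n)) {
    for (idx in combn(n, k, simplify = FALSE)) {
      g <- pool[idx]
      if (any(vapply(found, function(f) all(f %in% g), logical(1)))) next
      if (.joint_knockout_growth(community, g) < GROWTH_TOL)
        found[[length(found) + 1L]] <- g
    }
  }
  found
}

#' Format a screen report as an interaction table
#'
#' One row per active record, columns `compound`, `provides`, `consumes`,
#' `essential`, `robust`, `flux`, `group`; sorted essential-first, then by
#' flux descending, then by compound for full determinism.
#'
#' @param report a `screen_report`.
#' @param groups optional list of minimal jointly-essential groups (from
#'   [auto_groups()]) used to fill the `group` column.
#' @return a data frame.
#' @export
interaction_table <- function(report, groups = NULL) {
  rec <- report$records
  rec <- rec[rec$active, , drop = FALSE]
  grp <- rep(NA_character_, nrow(rec))
  if (!is.null(groups)) {
    for (g in groups) {
      lbl <- paste(sort(g), collapse = "+")
      grp[rec$metabolite %in% g] <- lbl
    }
  }
  out <- data.frame(compound = rec$compound_name, provides = rec$donor,
                    consumes = rec$recipient, essential = rec$essential,
                    robust = rec$direction_robust, flux = rec$transfer_flux,
                    group = grp, stringsAsFactors = FALSE)
  out <- out[order(-out$essential, -out$flux, out$compound), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read an interaction table TSV
#'
#' @param table data frame from [interaction_table()].
#' @param path destination TSV.
#' @return `path` (write) or the table (read).
#' @export
write_interaction_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_interaction_table
#' @export
read_interaction_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  tab$essential <- as.logical(tab$essential)
  tab$robust <- as.logical(tab$robust)
  if (is.null(tab$group)) tab$group <- NA_character_
  tab$group <- as.character(tab$group)
  tab
}
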