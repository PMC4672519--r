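#' Assemble the stoichiometric system of a model
#'
#' Builds the linear-programming data for flux balance analysis: the
#' stoichiometric matrix `S` (rows = metabolites, columns = reactions), flux
#' bound vectors `lb`/`ub`, and the objective weight vector `obj` (1 on the
#' biomass column).  When a medium is given, each exchange reaction's lower
#' bound is set to minus the medium's uptake bound for its metabolite's base
#' id, and to 0 for extracellular metabolites absent from the medium;
#' exchange upper bounds are left open so secretion is always allowed.  A
#' medium component with no matching exchange reaction raises a warning, not
#' an error.
#'
#' @param model a valid `metabolic_model`.
#' @param medium optional [medium()]; `NULL` leaves reaction bounds as stored.
#' @param extracellular id of the extracellular compartment.
#' @return an object of class `stoich_system`: list with `S`, `lb`, `ub`,
#'   `obj`, `b` (right-hand side, all zero), `row_ids`, `col_ids`.
#' @export
build_system <- function(model, medium = NULL, extracellular = "e") {
  assert_valid_model(model, extracellular)
  met_ids <- model$metabolites$id
  rxn_ids <- model$reactions$id
  S <- matrix(0, length(met_ids), length(rxn_ids),
              dimnames = list(met_ids, rxn_ids))
  for (rid in rxn_ids) {
    st <- model$stoichiometry[[rid]]
    S[names(st), rid] <- st
  }
  lb <- setNames(model$reactions$lower_bound, rxn_ids)
  ub <- setNames(model$reactions$upper_bound, rxn_ids)
  if (!is.null(medium)) {
    comp_of <- setNames(model$metabolites$compartment, met_ids)
    is_ex <- model$reactions$kind == "exchange"
    seen <- character()
    for (rid in rxn_ids[is_ex]) {
      mid <- names(model$stoichiometry[[rid]])
      base <- met_base_id(mid, comp_of[mid])
      if (base %in% names(medium$uptake_bounds)) {
        lb[rid] <- -medium$uptake_bounds[[base]]
        seen <- c(seen, base)
      } else {
        lb[rid] <- 0
      }
    }
    orphan <- setdiff(names(medium$uptake_bounds), seen)
    if (length(orphan))
      warning("medium component(s) with no exchange reaction in '", model$id,
              "': ", paste(orphan, collapse = ", "), call. = FALSE)
  }
  obj <- setNames(numeric(length(rxn_ids)), rxn_ids)
  if (!is.na(model$objective_reaction_id))
    obj[model$objective_reaction_id] <- 1
  structure(list(S = S, lb = lb, ub = ub, obj = obj,
                 b = setNames(numeric(length(met_ids)), met_ids),
                 row_ids = met_ids, col_ids = rxn_ids),
            class = "stoich_system")
}

#' @export
print.stoich_system <- function(x, ...) {
  cat("<stoich_system> ", length(x$row_ids), " rows x ", length(x$col_ids),
      " reactions; objective on ",
      paste(x$col_ids[x$obj != 0], collapse = ", "), "\n", sep = "")
  invisible(x)
}

.check_system <- function(system) {
  stopifnot(inherits(system, "stoich_system"))
  if (any(system$lb > system$ub))
    stop("system has lb > ub for: ",
         paste(system$col_ids[system$lb > system$ub], collapse = ", "),
         call. = FALSE)
  invisible(system)
}

.flux_solution <- function(status, objective, fluxes) {
  structure(list(status = status, objective_value = objective,
                 fluxes = fluxes), class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status: ", x$status, "; objective: ",
      format(x$objective_value), "\n", sep = "")
  invisible(x)
}

#' Flux balance analysis
#'
#' Maximises the objective `obj . v` subject to steady state `S v = 0` and
#' flux bounds `lb <= v <= ub`, using the package's compiled bounded-variable
#' simplex.  Optimal solutions satisfy the steady-state and bound
#' constraints to within 1e-6.
#'
#' @param system a `stoich_system` from [build_system()].
#' @return a `flux_solution` with fields `status` (`"optimal"`,
#'   `"infeasible"` or `"unbounded"`), `objective_value` (growth rate when
#'   the objective is biomass), and `fluxes` (named by reaction id).
#' @export
solve_fba <- function(system) {
  .check_system(system)
  res <- .cpp_simplex(system$S, system$b, system$obj, system$lb, system$ub,
                      TRUE, 50000L)
  if (res$status == "iteration_limit")
    stop("LP solver hit the iteration limit; system may be ill-conditioned",
         call. = FALSE)
  if (res$status != "optimal")
    return(.flux_solution(res$status, NA_real_,
                          setNames(rep(NA_real_, length(system$col_ids)),
                                   system$col_ids)))
  .flux_solution("optimal", res$objective,
                 setNames(as.numeric(res$x), system$col_ids))
}

#' Parsimonious flux balance analysis
#'
#' Among flux vectors achieving at least `(1 - relax)` times the FBA optimum,
#' returns one minimising the total absolute flux `sum(|v|)` (each reaction
#' split into two nonnegative directions).  This selects a canonical,
#' futile-cycle-free flux distribution from a possibly degenerate optimum and
#' is how transfer directions are assigned in the interaction screen.
#'
#' @param system a `stoich_system`.
#' @param relax relative optimality slack retained in the growth constraint.
#' @return a `flux_solution`; `objective_value` is the (near-optimal)
#'   objective of the returned fluxes, not the flux norm.
#' @export
solve_pfba <- function(system, relax = 1e-6) {
  .check_system(system)
  base <- solve_fba(system)
  if (base$status != "optimal") return(base)
  n <- length(system$col_ids)
  m <- length(system$row_ids)
  # v = p - q with p, q >= 0; minimise sum(p + q)
  A <- cbind(system$S, -system$S)
  lo_p <- pmax(system$lb, 0); hi_p <- pmax(system$ub, 0)
  lo_q <- pmax(-system$ub, 0); hi_q <- pmax(-system$lb, 0)
  # growth threshold row: obj.(p - q) - s = (1 - relax) * opt, s >= 0
  thr <- (1 - relax) * base$objective_value
  A <- rbind(A, c(system$obj, -system$obj))
  slack_col <- c(rep(0, m), -1)
  A <- cbind(A, slack_col)
  b <- c(system$b, thr)
  lb <- c(lo_p, lo_q, 0)
  ub <- c(hi_p, hi_q, Inf)
  cost <- c(rep(-1, 2 * n), 0)   # maximise -(sum p + sum q)
  res <- .cpp_simplex(A, b, cost, lb, ub, TRUE, 50000L)
  if (res$status != "optimal")
    stop("pFBA stage-two LP returned status ", res$status, call. = FALSE)
  v <- res$x[seq_len(n)] - res$x[n + seq_len(n)]
  fluxes <- setNames(as.numeric(v), system$col_ids)
  .flux_solution("optimal", sum(system$obj * fluxes), fluxes)
}

# optimise an arbitrary linear functional w.v subject to the system plus a
# growth threshold row; shared machinery for FVA and direction-robustness
.opt_functional <- function(system, w, fraction, optimum, maximize) {
  m <- length(system$row_ids)
  A <- rbind(system$S, system$obj)
  A <- cbind(A, c(rep(0, m), -1))
  b <- c(system$b, fraction * optimum)
  lb <- c(system$lb, 0)
  ub <- c(system$ub, Inf)
  res <- .cpp_simplex(A, b, c(w, 0), lb, ub, maximize, 50000L)
  if (res$status != "optimal")
    stop("FVA subproblem returned status ", res$status, call. = FALSE)
  res$objective
}

#' Flux variability analysis
#'
#' For each requested reaction, computes the minimum and maximum flux
#' attainable subject to the system constraints plus
#' `obj . v >= fraction_of_optimum * optimum`.
#'
#' @param system a `stoich_system`.
#' @param reaction_ids reactions to scan; default all.
#' @param fraction_of_optimum fraction of the FBA optimum to maintain,
#'   in `[0, 1]`.
#' @return data frame with columns `reaction`, `min_flux`, `max_flux`.
#' @export
fva <- function(system, reaction_ids = system$col_ids,
                fraction_of_optimum = 1.0) {
  stopifnot(fraction_of_optimum >= 0, fraction_of_optimum <= 1)
  .check_system(system)
  unknown <- setdiff(reaction_ids, system$col_ids)
  if (length(unknown))
    stop("unknown reaction id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  base <- solve_fba(system)
  if (base$status != "optimal")
    stop("FVA requires an optimal base solution; got ", base$status,
         call. = FALSE)
  n <- length(system$col_ids)
  out <- data.frame(reaction = reaction_ids, min_flux = NA_real_,
                    max_flux = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(reaction_ids)) {
    w <- numeric(n)
    w[match(reaction_ids[i], system$col_ids)] <- 1
    out$min_flux[i] <- .opt_functional(system, w, fraction_of_optimum,
                                       base$objective_value, FALSE)
    out$max_flux[i] <- .opt_functional(system, w, fraction_of_optimum,
                                       base$objective_value, TRUE)
  }
  out
}

#' Knock out reactions
#'
#' Returns a copy of the system with `lb = ub = 0` for each listed reaction;
#' the input is untouched.
#'
#' @param system a `stoich_system`.
#' @param reaction_ids reactions to disable (may be empty).
#' @return the modified copy.
#' @export
knockout <- function(system, reaction_ids) {
  unknown <- setdiff(reaction_ids, system$col_ids)
  if (length(unknown))
    stop("unknown reaction id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  system$lb[reaction_ids] <- 0
  system$ub[reaction_ids] <- 0
  system
}

#' Write a TSV flux report
#'
#' @param system the solved `stoich_system`.
#' @param solution a `flux_solution` for that system.
#' @param path destination TSV (`reaction`, `flux`, `lb`, `ub`).
#' @return `path`, invisibly.
#' @export
write_flux_report <- function(system, solution, path) {
  tab <- data.frame(reaction = system$col_ids,
                    flux = unname(solution$fluxes[system$col_ids]),
                    lb = unname(system$lb), ub = unname(system$ub))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Brute-force LP optimum by basic-solution enumeration
#'
#' Independent verification oracle for [solve_fba()] on tiny systems: it
#' enumerates every basic solution of `{S v = 0, lb <= v <= ub}` by fixing
#' each subset of `n - rank(S)` variables at a bound combination, solving the
#' equality system for the rest, and keeping feasible points.  The optimum of
#' a bounded feasible LP is attained at one of these points.  Exponential in
#' the reaction count; refuse anything beyond `max_reactions`.
#'
#' @param system a `stoich_system` with few reactions.
#' @param max_reactions guard on problem size.
#' @return list with `feasible` and `objective` (`-Inf` if infeasible).
#' @export
fba_enumerate_optimum <- function(system, max_reactions = 8) {
  n <- length(system$col_ids)
  if (n > max_reactions)
    stop("enumeration oracle limited to ", max_reactions, " reactions",
         call. = FALSE)
  A <- system$S; b <- system$b
  lb <- unname(system$lb); ub <- unname(system$ub); cc <- unname(system$obj)
  r <- qr(A)$rank
  nfree <- n - r
  best <- -Inf; feas <- FALSE
  subsets <- if (nfree == 0) list(integer(0))
             else combn(n, nfree, simplify = FALSE)
  for (fix in subsets) {
    grid <- if (length(fix)) expand.grid(rep(list(c(FALSE, TRUE)), length(fix)))
            else data.frame(row.names = 1)
    for (g in seq_len(max(1L, nrow(grid)))) {
      v <- rep(NA_real_, n)
      if (length(fix))
        v[fix] <- ifelse(unlist(grid[g, ]), ub[fix], lb[fix])
      rest <- setdiff(seq_len(n), fix)
      rhs <- b - if (length(fix)) A[, fix, drop = FALSE] %*% v[fix] else 0
      if (length(rest)) {
        sol <- tryCatch(qr.solve(A[, rest, drop = FALSE], rhs),
                        error = function(e) NULL)
        if (is.null(sol)) next
        v[rest] <- sol
      }
      if (any(!is.finite(v))) next
      if (max(abs(A %*% v - b)) > 1e-7) next
      if (any(v < lb - 1e-7) || any(v > ub + 1e-7)) next
      feas <- TRUE
      best <- max(best, sum(cc * v))
    }
  }
  list(feasible = feas, objective = best)
}
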