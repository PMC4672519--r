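# Independent oracles and shared helpers for the suite.

# feasibility certificate: steady state and bounds within 1e-6 on every
# optimal solution
expect_valid_solution <- function(system, solution, tol = 1e-6) {
  expect_identical(solution$status, "optimal")
  v <- solution$fluxes[system$col_ids]
  expect_lt(max(abs(system$S %*% v - system$b)), tol)
  expect_true(all(v >= system$lb - tol))
  expect_true(all(v <= system$ub + tol))
  invisible(solution)
}

# brute-force bidirectional-best-hit oracle, written independently of
# kmer_bbh(): all-vs-all Jaccard over k-mer sets, then mutual unique argmax
oracle_bbh <- function(query, reference, k, min_score) {
  kmers <- function(s) {
    if (nchar(s) < k) return(character())
    unique(vapply(seq_len(nchar(s) - k + 1), function(i)
      substr(s, i, i + k - 1), character(1)))
  }
  qs <- lapply(query, kmers); rs <- lapply(reference, kmers)
  jac <- function(a, b) {
    u <- length(unique(c(a, b)))
    if (u == 0) 0 else sum(a %in% b) / u
  }
  out <- data.frame(query_gene = character(), reference_gene = character(),
                    score = numeric(), stringsAsFactors = FALSE)
  for (qi in names(qs)) for (ri in names(rs)) {
    s <- jac(qs[[qi]], rs[[ri]])
    if (s < min_score) next
    s_q <- vapply(names(rs), function(r2) jac(qs[[qi]], rs[[r2]]), numeric(1))
    s_r <- vapply(names(qs), function(q2) jac(qs[[q2]], rs[[ri]]), numeric(1))
    if (sum(s_q >= s - 1e-12) == 1 && sum(s_r >= s - 1e-12) == 1)
      out <- rbind(out, data.frame(query_gene = qi, reference_gene = ri,
                                   score = s, stringsAsFactors = FALSE))
  }
  out[order(-out$score, out$query_gene), , drop = FALSE]
}

# the milk fixture is deterministic; share one copy across tests
milk <- make_milk_fixture()
milk_community <- suppressWarnings(
  build_community(milk$st, milk$lr, milk$medium))

# closed-form optima of the curated fixture (bottleneck arithmetic):
# ST alone on milk: 10 lactose -> 10 glucose -> 40 carbon units;
#   biomass + folate + purine synthesis drain 10.3 carbon per growth unit
MU_ST_MONO <- 40 / 10.3
# community: ST additionally supplies LR's folate (0.1) and purine via
#   xanthine/guanine (0.2) per unit of the common growth rate
MU_COMMUNITY <- 40 / 10.6

# a toy with two equivalent parallel routes from substrate to biomass
make_parallel_model <- function(uptake = 10) {
  m <- crossfeedr:::.empty_model("PARALLEL")
  m <- add_metabolite(m, "substrate_e", "e", "substrate")
  m <- add_metabolite(m, "substrate_c", "c", "substrate")
  m <- add_metabolite(m, "mid_c", "c", "intermediate")
  m <- add_reaction(m, "EX_substrate_e", c(substrate_e = -1), -uptake, 1000,
                    kind = "exchange")
  m <- add_reaction(m, "SUBt", c(substrate_e = -1, substrate_c = 1), 0, 1000,
                    kind = "transport")
  m <- add_reaction(m, "PATH1", c(substrate_c = -1, mid_c = 1), 0, 1000,
                    kind = "internal")
  m <- add_reaction(m, "PATH2", c(substrate_c = -1, mid_c = 1), 0, 1000,
                    kind = "internal")
  m <- add_reaction(m, "BIO", c(mid_c = -1), 0, 1000, kind = "biomass")
  m$objective_reaction_id <- "BIO"
  assert_valid_model(m)
  m
}
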