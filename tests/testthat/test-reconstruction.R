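test_that("kmer_bbh pairs identical sequences at score 1 and none for disjoint k-mers", {
  q <- c(q1 = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ")
  r <- c(r1 = q[[1]])
  got <- kmer_bbh(q, r, k = 5, min_score = 0.3)
  expect_equal(got$score, 1.0)
  expect_identical(got$query_gene, "q1")

  disjoint <- kmer_bbh(c(q1 = "AAAAAAAAAA"), c(r1 = "WWWWWWWWWW"), k = 5,
                       min_score = 0.05)
  expect_equal(nrow(disjoint), 0)

  expect_error(kmer_bbh(c(q1 = ""), r, k = 5, min_score = 0.3), "empty")
})

test_that("kmer_bbh matches the brute-force mutual-best-hit oracle on mutated copies", {
  for (seed in c(1, 7)) {
    g <- make_toy_genomes(seed, n_genes = 5, mutation_rate = 0.15,
                          n_decoys = 2)
    got <- kmer_bbh(g$query, g$reference, k = 5, min_score = 0.05)
    want <- oracle_bbh(g$query, g$reference, k = 5, min_score = 0.05)
    expect_equal(got$query_gene, want$query_gene)
    expect_equal(got$reference_gene, want$reference_gene)
    expect_equal(got$score, want$score, tolerance = 1e-12)
  }
})

test_that("kmer_bbh is symmetric under swapping query and reference", {
  g <- make_toy_genomes(3, n_genes = 4, mutation_rate = 0.2, n_decoys = 1)
  fwd <- kmer_bbh(g$query, g$reference, k = 5, min_score = 0.05)
  rev <- kmer_bbh(g$reference, g$query, k = 5, min_score = 0.05)
  expect_setequal(paste(fwd$query_gene, fwd$reference_gene),
                  paste(rev$reference_gene, rev$query_gene))
  expect_equal(sort(fwd$score), sort(rev$score))
})

test_that("bbh recall does not increase with mutation rate", {
  recalls <- vapply(c(0, 0.15, 0.3, 0.45), function(mu) {
    g <- make_toy_genomes(11, n_genes = 6, mutation_rate = mu, n_decoys = 2)
    got <- kmer_bbh(g$query, g$reference, k = 5, min_score = 0.05)
    truth <- paste(g$true_map$query_gene, g$true_map$reference_gene)
    sum(paste(got$query_gene, got$reference_gene) %in% truth) / length(truth)
  }, numeric(1))
  expect_equal(recalls[1], 1)   # mutation-free copies are exact best hits
  expect_true(all(diff(recalls) <= 1e-12))
})

test_that("gene rule transfer follows the boolean truth table", {
  ref <- make_chain_model("REF")
  ref <- add_metabolite(ref, "x_c", "c", "x")
  ref <- add_reaction(ref, "R_A", c(substrate_c = -1, x_c = 1),
                      gene_rule = "gA", kind = "internal")
  ref <- add_reaction(ref, "R_AND", c(substrate_c = -1, x_c = 1),
                      gene_rule = "gA and gB", kind = "internal")
  ref <- add_reaction(ref, "R_OR", c(substrate_c = -1, x_c = 1),
                      gene_rule = "gA or gB", kind = "internal")
  ref$genes <- c("gA", "gB")
  assert_valid_model(ref)

  pairs <- data.frame(query_gene = "qA", reference_gene = "gA", score = 0.9)
  draft <- transfer_reactions(ref, pairs, "QUERY")
  kept <- setdiff(draft$reactions$id, "BIO")
  expect_setequal(kept, c("R_A", "R_OR"))       # AND branch fails
  expect_identical(draft$reactions$gene_rule[draft$reactions$id == "R_A"],
                   "qA")
  expect_true("BIO" %in% draft$reactions$id)    # biomass always carried

  expect_error(
    transfer_reactions(ref, data.frame(query_gene = "q", reference_gene = "gZ",
                                       score = 0.5), "Q"),
    "unknown reference gene")
})

test_that("self-transfer plus non-gene addition reproduces the reference exactly", {
  ref <- milk$st
  idmap <- data.frame(query_gene = ref$genes, reference_gene = ref$genes,
                      score = 1.0)
  draft <- transfer_reactions(ref, idmap, ref$id)
  draft <- add_non_gene_reactions(draft, ref)
  expect_setequal(draft$reactions$id, ref$reactions$id)
  expect_true(models_equal(draft, ref))
})

test_that("an empty ortholog map transfers only biomass", {
  empty <- data.frame(query_gene = character(), reference_gene = character(),
                      score = numeric())
  draft <- transfer_reactions(milk$st, empty, "EMPTY")
  expect_identical(draft$reactions$id, "BIOMASS_ST")
})

test_that("adding ortholog pairs never shrinks the transferred reaction set", {
  ref <- milk$lr
  genes <- sort(ref$genes)
  kept_prev <- character()
  for (k in c(3, 7, 11, length(genes))) {
    pairs <- data.frame(query_gene = paste0("q_", genes[seq_len(k)]),
                        reference_gene = genes[seq_len(k)], score = 1)
    kept <- transfer_reactions(ref, pairs, "Q")$reactions$id
    expect_true(all(kept_prev %in% kept))
    kept_prev <- kept
  }
})

test_that("non-gene reaction addition is counted, idempotent and conflict-checked", {
  ref <- milk$st
  no_gene <- sum(is.na(ref$reactions$gene_rule))
  draft <- transfer_reactions(
    ref, data.frame(query_gene = character(), reference_gene = character(),
                    score = numeric()), "D")
  aug <- add_non_gene_reactions(draft, ref)
  # biomass was already present; every other non-gene reaction is gained
  expect_equal(nrow(aug$reactions), no_gene)
  expect_true(all(ref$reactions$id[ref$reactions$kind == "exchange"] %in%
                    aug$reactions$id))
  again <- add_non_gene_reactions(aug, ref)
  expect_true(models_equal(again, aug))

  clash <- ref
  clash$stoichiometry[["GALtx"]] <- c(galactose_c = -2, galactose_e = 2)
  expect_error(add_non_gene_reactions(aug, clash), "collision")
})

test_that("subsystem copying is exact, validated, and order-independent", {
  ref <- milk$st
  ref$reactions$subsystem[ref$reactions$id %in% c("FOLS", "PURS")] <-
    "vitamin and purine biosynthesis"
  ref$reactions$subsystem[ref$reactions$id == "LACZ"] <- "lactose catabolism"
  assert_valid_model(ref)
  base <- transfer_reactions(
    ref, data.frame(query_gene = "q1", reference_gene = "lacS", score = 1), "D")

  copied <- copy_subsystems(base, ref, "vitamin and purine biosynthesis")
  expect_setequal(setdiff(copied$reactions$id, base$reactions$id),
                  c("FOLS", "PURS"))
  expect_true(models_equal(copy_subsystems(base, ref, character()), base))
  expect_error(copy_subsystems(base, ref, "no such pathway"),
               "unknown subsystem")

  # copy-then-add vs add-then-copy give the same reaction set
  ab <- add_non_gene_reactions(
    copy_subsystems(base, ref, "lactose catabolism"), ref)
  ba <- copy_subsystems(
    add_non_gene_reactions(base, ref), ref, "lactose catabolism")
  expect_setequal(ab$reactions$id, ba$reactions$id)
})

test_that("protein FASTA and ortholog tables round-trip", {
  g <- make_toy_genomes(2, n_genes = 3, mutation_rate = 0.1, n_decoys = 0)
  fa <- withr::local_tempfile(fileext = ".faa")
  writeLines(paste0(">", names(g$reference), "\n", g$reference), fa)
  back <- read_protein_fasta(fa)
  expect_identical(back[names(g$reference)], g$reference)

  pairs <- kmer_bbh(g$query, g$reference, k = 5, min_score = 0.05)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_ortholog_table(pairs, tsv)
  expect_equal(read_ortholog_table(tsv), pairs, ignore_attr = TRUE)
})
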