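# Synthetic models: a hand-curated two-member milk consortium mini-fixture
# emulating a proteolytic, lactose-fermenting Streptococcus-like member and a
# folate/purine-auxotrophic, lactose/casein-negative Lactobacillus-like
# member, plus seeded toy generators with planted ground truth.

.VITAMINS <- c("biotin", "nicotinate", "pantothenate", "pyridoxamine",
               "riboflavin", "thiamin")

# run fn under a temporary seed without disturbing the caller's RNG stream
.with_seed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  fn()
}

.add_exchanges <- function(model, extracellular = "e") {
  emets <- model$metabolites$id[model$metabolites$compartment == extracellular]
  for (mid in emets) {
    base <- met_base_id(mid, extracellular)
    model <- add_reaction(model, paste0("EX_", base, "_e"),
                          setNames(-1, mid), lower_bound = 0,
                          upper_bound = 1000, kind = "exchange",
                          name = paste(base, "exchange"))
  }
  model
}

#' The milk mini-consortium fixture
#'
#' Returns the hand-curated deterministic two-member fixture used throughout
#' the package: a *S. thermophilus*-like member (`ST_C106_mini`) that imports
#' and hydrolyses lactose (secreting the galactose moiety it cannot
#' catabolise), degrades milk peptides through a cell-wall protease,
#' synthesises folate, xanthine and guanine, and secretes succinate and
#' glycerol as fixed fermentation by-products; and a *L. rhamnosus*-like
#' member (`LR_yoba_mini`) that cannot use lactose or milk peptides, is
#' auxotrophic for folate and purines, and grows on galactose, succinate or
#' glycerol as interchangeable carbon sources.  Both members require the
#' B-vitamins and phosphate of the milk medium.  Biomass is a single lumped
#' reaction draining one stoichiometric bundle of precursors.
#'
#' The same models and medium are shipped as files under
#' `inst/extdata/milk_consortium_mini/`.
#'
#' @return list with elements `st`, `lr` (validated `metabolic_model`s) and
#'   `medium` (the 10-component milk medium).
#' @export
make_milk_fixture <- function() {
  vit_c <- paste0(.VITAMINS, "_c")
  bio_needs <- c(carbon_c = -10, amino_acids_c = -2, folate_c = -0.1,
                 purine_c = -0.2, setNames(rep(-0.1, 6), vit_c),
                 phosphate_c = -0.5)

  ## ---- ST-like member -----------------------------------------------------
  st <- .empty_model("ST_C106_mini")
  emet <- function(m, base, ann = NA) add_metabolite(m, paste0(base, "_e"),
                                                     "e", base, annotation = ann)
  cmet <- function(m, base) add_metabolite(m, paste0(base, "_c"), "c", base)
  st <- emet(st, "lactose", "Lactose")
  st <- emet(st, "milk_peptides", "Milk peptides (casein-derived)")
  st <- emet(st, "free_peptides", "Peptides")
  st <- emet(st, "galactose", "Galactose")
  st <- emet(st, "succinate", "Succinate")
  st <- emet(st, "glycerol", "Glycerol")
  st <- emet(st, "folate", "Folic acid")
  st <- emet(st, "xanthine", "Xanthine/Guanine")
  st <- emet(st, "guanine", "Xanthine/Guanine")
  for (v in .VITAMINS) st <- emet(st, v)
  st <- emet(st, "phosphate")
  st <- emet(st, "water")
  for (b in c("lactose", "glucose", "galactose", "carbon", "free_peptides",
              "amino_acids", "succinate", "glycerol", "folate", "purine",
              "xanthine", "guanine", .VITAMINS, "phosphate"))
    st <- cmet(st, b)

  tr <- function(m, id, from, to, n_to = 1, gene = NA, name = id)
    add_reaction(m, id, setNames(c(-1, n_to), c(from, to)), 0, 1000,
                 gene_rule = gene, kind = "transport", name = name)
  st <- tr(st, "LCTSt", "lactose_e", "lactose_c", gene = "lacS",
           name = "lactose transporter (lacS)")
  st <- tr(st, "PEPTt_ST", "free_peptides_e", "free_peptides_c",
           gene = "oppA and oppB", name = "oligopeptide ABC transporter")
  st <- tr(st, "GALtx", "galactose_c", "galactose_e",
           name = "galactose efflux")
  st <- tr(st, "SUCCtx", "succinate_c", "succinate_e",
           name = "succinate efflux")
  st <- tr(st, "GLYCtx", "glycerol_c", "glycerol_e", name = "glycerol efflux")
  st <- tr(st, "FOLtx", "folate_c", "folate_e", name = "folate efflux")
  st <- tr(st, "XANtx", "xanthine_c", "xanthine_e", name = "xanthine efflux")
  st <- tr(st, "GUAtx", "guanine_c", "guanine_e", name = "guanine efflux")
  for (v in c(.VITAMINS, "phosphate"))
    st <- tr(st, paste0(toupper(substr(v, 1, 4)), "t_ST"),
             paste0(v, "_e"), paste0(v, "_c"), name = paste(v, "uptake"))

  st <- add_reaction(st, "PRTS",
                     c(milk_peptides_e = -1, free_peptides_e = 3), 0, 1000,
                     gene_rule = "prtS", kind = "internal",
                     name = "cell-wall casein protease (prtS)")
  st <- add_reaction(st, "LACZ", c(lactose_c = -1, glucose_c = 1,
                                   galactose_c = 1), 0, 1000,
                     gene_rule = "lacZ", kind = "internal",
                     name = "beta-galactosidase (lacZ)")
  st <- add_reaction(st, "GLYCOL_ST",
                     c(glucose_c = -1, carbon_c = 4, succinate_c = 1,
                       glycerol_c = 1), 0, 1000, gene_rule = "glk",
                     kind = "internal",
                     name = "glucose fermentation with by-products")
  st <- add_reaction(st, "PEPD_ST", c(free_peptides_c = -1, amino_acids_c = 2),
                     0, 1000, gene_rule = "pepN", kind = "internal",
                     name = "peptidase")
  st <- add_reaction(st, "FOLS", c(carbon_c = -1, folate_c = 1), 0, 1000,
                     gene_rule = "folP", kind = "internal",
                     name = "folate biosynthesis")
  st <- add_reaction(st, "PURS", c(carbon_c = -1, purine_c = 1), 0, 1000,
                     gene_rule = "purA", kind = "internal",
                     name = "purine biosynthesis")
  st <- add_reaction(st, "XANS", c(carbon_c = -1, xanthine_c = 1), 0, 1000,
                     gene_rule = "xdh", kind = "internal",
                     name = "xanthine biosynthesis")
  st <- add_reaction(st, "GUAS", c(carbon_c = -1, guanine_c = 1), 0, 1000,
                     gene_rule = "guaB", kind = "internal",
                     name = "guanine biosynthesis")
  st <- add_reaction(st, "BIOMASS_ST", bio_needs, 0, 1000, kind = "biomass",
                     name = "lumped biomass")
  st$genes <- c("lacS", "lacZ", "prtS", "oppA", "oppB", "pepN", "glk",
                "folP", "purA", "xdh", "guaB")
  st$objective_reaction_id <- "BIOMASS_ST"
  st <- .add_exchanges(st)
  assert_valid_model(st)

  ## ---- LR-like member -----------------------------------------------------
  lr <- .empty_model("LR_yoba_mini")
  lr <- emet(lr, "galactose", "Galactose")
  lr <- emet(lr, "glucose", "Glucose")
  lr <- emet(lr, "succinate", "Succinate")
  lr <- emet(lr, "glycerol", "Glycerol")
  lr <- emet(lr, "free_peptides", "Peptides")
  lr <- emet(lr, "amino_acids", "Amino acids")
  lr <- emet(lr, "folate", "Folic acid")
  lr <- emet(lr, "xanthine", "Xanthine/Guanine")
  lr <- emet(lr, "guanine", "Xanthine/Guanine")
  for (v in .VITAMINS) lr <- emet(lr, v)
  lr <- emet(lr, "phosphate")
  lr <- emet(lr, "water")
  for (b in c("galactose", "glucose", "carbon", "succinate", "glycerol",
              "free_peptides", "amino_acids", "folate", "purine", "xanthine",
              "guanine", .VITAMINS, "phosphate"))
    lr <- cmet(lr, b)

  lr <- tr(lr, "GALt", "galactose_e", "galactose_c", gene = "galP",
           name = "galactose permease")
  lr <- tr(lr, "GLCt", "glucose_e", "glucose_c", gene = "glcU",
           name = "glucose permease")
  lr <- tr(lr, "SUCCt", "succinate_e", "succinate_c", gene = "dctA",
           name = "succinate uptake")
  lr <- tr(lr, "GLYCt", "glycerol_e", "glycerol_c", gene = "glpF",
           name = "glycerol facilitator")
  lr <- tr(lr, "PEPTt_LR", "free_peptides_e", "free_peptides_c",
           gene = "oppA_LR", name = "oligopeptide ABC transporter")
  lr <- tr(lr, "AAt", "amino_acids_e", "amino_acids_c",
           name = "amino acid uptake")
  lr <- tr(lr, "FOLt", "folate_e", "folate_c", gene = "folT",
           name = "folate transporter")
  lr <- tr(lr, "XANt", "xanthine_e", "xanthine_c", gene = "pbuX",
           name = "xanthine permease")
  lr <- tr(lr, "GUAt", "guanine_e", "guanine_c", gene = "pbuG",
           name = "guanine permease")
  for (v in c(.VITAMINS, "phosphate"))
    lr <- tr(lr, paste0(toupper(substr(v, 1, 4)), "t_LR"),
             paste0(v, "_e"), paste0(v, "_c"), name = paste(v, "uptake"))

  lr <- add_reaction(lr, "GALK", c(galactose_c = -1, carbon_c = 2), 0, 1000,
                     gene_rule = "galK", kind = "internal",
                     name = "galactose catabolism")
  lr <- add_reaction(lr, "GLCK", c(glucose_c = -1, carbon_c = 4), 0, 1000,
                     gene_rule = "glk_LR", kind = "internal",
                     name = "glucose catabolism")
  lr <- add_reaction(lr, "SUCD", c(succinate_c = -1, carbon_c = 1), 0, 1000,
                     gene_rule = "sdhA", kind = "internal",
                     name = "succinate catabolism")
  lr <- add_reaction(lr, "GLYD", c(glycerol_c = -1, carbon_c = 1), 0, 1000,
                     gene_rule = "glpK", kind = "internal",
                     name = "glycerol catabolism")
  lr <- add_reaction(lr, "PEPD_LR", c(free_peptides_c = -1, amino_acids_c = 2),
                     0, 1000, gene_rule = "pepX", kind = "internal",
                     name = "peptidase")
  lr <- add_reaction(lr, "XPT", c(xanthine_c = -1, purine_c = 1), 0, 1000,
                     gene_rule = "xpt", kind = "internal",
                     name = "xanthine salvage")
  lr <- add_reaction(lr, "GPT", c(guanine_c = -1, purine_c = 1), 0, 1000,
                     gene_rule = "hpt", kind = "internal",
                     name = "guanine salvage")
  lr <- add_reaction(lr, "BIOMASS_LR", bio_needs, 0, 1000, kind = "biomass",
                     name = "lumped biomass")
  lr$genes <- c("galP", "glcU", "dctA", "glpF", "oppA_LR", "folT", "pbuX",
                "pbuG", "galK", "glk_LR", "sdhA", "glpK", "pepX", "xpt", "hpt")
  lr$objective_reaction_id <- "BIOMASS_LR"
  lr <- .add_exchanges(lr)
  assert_valid_model(lr)

  med <- milk_medium()
  list(st = st, lr = lr, medium = med)
}

#' The milk medium
#'
#' The 10-component defined milk medium: lactose and casein-derived milk
#' peptides as carbon and nitrogen sources, the B-vitamins biotin,
#' nicotinate, pantothenate, pyridoxamine, riboflavin and thiamin, phosphate,
#' and water.  Nutrient uptake bounds default to 10 mmol/gDW/h, water is
#' unconstrained; the paper-scale milk composition is nutrient-level, so one
#' common bound is used for all limiting components.
#'
#' @param bound uptake bound applied to every nutrient component.
#' @return a [medium()].
#' @export
milk_medium <- function(bound = 10) {
  comp <- setNames(rep(bound, 9),
                   c("biotin", "lactose", "milk_peptides", "nicotinate",
                     "pantothenate", "phosphate", "pyridoxamine",
                     "riboflavin", "thiamin"))
  medium(c(comp, water = 1000), name = "milk")
}

#' A linear-chain toy model
#'
#' Exchange -> transport -> biomass with unit coefficients: the smallest
#' growing model, used in examples and tests.  The uptake bound is the
#' single bottleneck, so the FBA optimum equals `uptake`.
#'
#' @param id model id.
#' @param uptake exchange lower bound magnitude.
#' @return a validated `metabolic_model`.
#' @export
make_chain_model <- function(id = "CHAIN", uptake = 10) {
  m <- .empty_model(id)
  m <- add_metabolite(m, "substrate_e", "e", "substrate")
  m <- add_metabolite(m, "substrate_c", "c", "substrate")
  m <- add_reaction(m, "EX_substrate_e", c(substrate_e = -1), -uptake, 1000,
                    kind = "exchange")
  m <- add_reaction(m, "SUBt", c(substrate_e = -1, substrate_c = 1), 0, 1000,
                    kind = "transport")
  m <- add_reaction(m, "BIO", c(substrate_c = -1), 0, 1000, kind = "biomass")
  m$objective_reaction_id <- "BIO"
  assert_valid_model(m)
  m
}

#' Generator configuration for synthetic community pairs
#'
#' @param n_essential number of individually essential planted transfers.
#' @param n_redundant_paths number of planted redundancy (OR) groups; each
#'   group's metabolites are interchangeable suppliers of one biomass
#'   precursor of member B.
#' @param n_extra_metabolites number of shared-but-unused metabolites (both
#'   members carry transporters; B has no use for them).
#' @param noise_reactions number of random mass-balanced reactions added to
#'   member A that cannot create growth shortcuts.
#' @param seed RNG seed; identical seeds give byte-identical serialized
#'   output.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_essential = 2, n_redundant_paths = 1,
                             n_extra_metabolites = 1, noise_reactions = 0,
                             seed = 1) {
  stopifnot(n_essential >= 0, n_redundant_paths >= 0,
            n_extra_metabolites >= 0, noise_reactions >= 0)
  structure(list(n_essential = n_essential,
                 n_redundant_paths = n_redundant_paths,
                 n_extra_metabolites = n_extra_metabolites,
                 noise_reactions = noise_reactions, seed = seed),
            class = "generator_config")
}

#' Generate a toy community pair with planted ground truth
#'
#' Member A catabolises the medium's sole polymer substrate and synthesises
#' and exports every transfer metabolite; member B cannot touch the
#' substrate and requires, per biomass unit, each planted essential transfer
#' plus one precursor per redundancy group, obtainable interchangeably from
#' any group member.  Extra shared metabolites are transportable but
#' useless.  Noise reactions are reversible conversions between fresh
#' dead-end metabolites of A (mass-balanced, provably unable to carry
#' steady-state flux); the generator additionally verifies that mono and
#' community growth are unchanged before accepting them.
#'
#' @param config a [generator_config()].
#' @return list with `a`, `b` (models), `medium`, and `truth` (a
#'   `planted_truth` list: `essential_transfers` data frame, `or_groups`
#'   list, `inactive_shared` character vector).
#' @export
make_toy_pair <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  .with_seed(config$seed, function() .build_toy_pair(config))
}

.build_toy_pair <- function(config) {
  if (config$n_essential == 0 && config$n_redundant_paths == 0)
    stop("contradictory generator config: no planted transfers means member ",
         "B has no biomass requirement", call. = FALSE)
  ess <- if (config$n_essential) paste0("ess", seq_len(config$n_essential))
         else character()
  groups <- list()
  if (config$n_redundant_paths)
    for (g in seq_len(config$n_redundant_paths))
      groups[[g]] <- paste0("grp", g, letters[seq_len(sample(2:3, 1))])
  extras <- if (config$n_extra_metabolites)
    paste0("extra", seq_len(config$n_extra_metabolites)) else character()
  transfer <- c(ess, unlist(groups), extras)

  a <- .empty_model("SYN_A")
  a <- add_metabolite(a, "substrate_e", "e", "substrate")
  a <- add_metabolite(a, "substrate_c", "c", "substrate")
  a <- add_metabolite(a, "carbon_c", "c", "carbon")
  for (t in transfer) {
    a <- add_metabolite(a, paste0(t, "_e"), "e", t)
    a <- add_metabolite(a, paste0(t, "_c"), "c", t)
  }
  a <- add_reaction(a, "SUBt_A", c(substrate_e = -1, substrate_c = 1), 0, 1000,
                    kind = "transport")
  a <- add_reaction(a, "CAT_A", c(substrate_c = -1, carbon_c = 4), 0, 1000,
                    kind = "internal")
  for (t in transfer) {
    a <- add_reaction(a, paste0("SYN_", t),
                      setNames(c(-1, 1), c("carbon_c", paste0(t, "_c"))),
                      0, 1000, kind = "internal")
    a <- add_reaction(a, paste0("EXP_", t),
                      setNames(c(-1, 1), paste0(t, c("_c", "_e"))),
                      0, 1000, kind = "transport")
  }
  a <- add_reaction(a, "BIOMASS_A", c(carbon_c = -2), 0, 1000,
                    kind = "biomass")
  a$objective_reaction_id <- "BIOMASS_A"
  a <- .add_exchanges(a)
  assert_valid_model(a)

  b <- .empty_model("SYN_B")
  bio <- c()
  for (t in transfer) {
    b <- add_metabolite(b, paste0(t, "_e"), "e", t)
    b <- add_metabolite(b, paste0(t, "_c"), "c", t)
  }
  for (gi in seq_along(groups))
    b <- add_metabolite(b, paste0("gprec", gi, "_c"), "c",
                        paste0("group-", gi, " precursor"))
  for (t in transfer)
    b <- add_reaction(b, paste0("T_", t),
                      setNames(c(-1, 1), paste0(t, c("_e", "_c"))),
                      0, 1000, kind = "transport")
  for (t in ess) bio[paste0(t, "_c")] <- -1
  for (gi in seq_along(groups)) {
    for (t in groups[[gi]])
      b <- add_reaction(b, paste0("CONV_", t),
                        setNames(c(-1, 1),
                                 c(paste0(t, "_c"), paste0("gprec", gi, "_c"))),
                        0, 1000, kind = "internal")
    bio[paste0("gprec", gi, "_c")] <- -1
  }
  if (!length(bio)) bio <- c(ess1_c = -1)  # degenerate config guard
  b <- add_reaction(b, "BIOMASS_B", bio, 0, 1000, kind = "biomass")
  b$objective_reaction_id <- "BIOMASS_B"
  b <- .add_exchanges(b)
  assert_valid_model(b)

  med <- medium(c(substrate = 10), name = "synthetic substrate medium")

  # noise honesty: growth of A must be identical before and after noise
  if (config$noise_reactions > 0) {
    g0 <- mono_growth(a, med)
    a <- .add_noise_reactions(a, config$noise_reactions)
    assert_valid_model(a)
    g1 <- mono_growth(a, med)
    stopifnot(abs(g0 - g1) < 1e-9)
  }

  truth <- structure(
    list(essential_transfers = data.frame(
           metabolite = ess,
           donor = rep("SYN_A", length(ess)),
           recipient = rep("SYN_B", length(ess)), stringsAsFactors = FALSE),
         or_groups = lapply(groups, sort),
         inactive_shared = extras),
    class = "planted_truth")
  list(a = a, b = b, medium = med, truth = truth)
}

# reversible conversions between fresh dead-end metabolite pairs: balanced,
# disconnected from the growing network, provably zero-flux at steady state
.add_noise_reactions <- function(model, n) {
  if (n == 0) return(model)
  for (i in seq_len(n)) {
    m1 <- paste0("noise", i, "a_c"); m2 <- paste0("noise", i, "b_c")
    model <- add_metabolite(model, m1, "c", m1)
    model <- add_metabolite(model, m2, "c", m2)
    k <- sample(1:3, 1)
    model <- add_reaction(model, paste0("NOISE_", i),
                          setNames(c(-1, k), c(m1, m2)), -1000, 1000,
                          kind = "internal")
  }
  model
}

#' Generate toy protein sets with a known ortholog map
#'
#' Reference proteins are random amino-acid sequences; query proteins are
#' point-mutated copies (the true orthologs) plus unrelated decoy sequences.
#'
#' @param seed RNG seed.
#' @param n_genes number of true ortholog pairs.
#' @param mutation_rate per-residue substitution probability in `[0, 0.5]`.
#' @param n_decoys number of unrelated query decoys.
#' @param length_range range of sequence lengths.
#' @return list with `query`, `reference` (named character vectors) and
#'   `true_map` (data frame `query_gene`, `reference_gene`).
#' @export
make_toy_genomes <- function(seed, n_genes = 5, mutation_rate = 0.1,
                             n_decoys = 2, length_range = c(80, 120)) {
  stopifnot(mutation_rate >= 0, mutation_rate <= 0.5, n_genes >= 0)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  .with_seed(seed, function() {
    rand_seq <- function()
      paste(sample(aa, sample(length_range[1]:length_range[2], 1),
                   replace = TRUE), collapse = "")
    reference <- setNames(
      vapply(seq_len(n_genes), function(i) rand_seq(), character(1)),
      if (n_genes) paste0("ref", seq_len(n_genes)) else character())
    query <- vapply(reference, function(s) {
      ch <- strsplit(s, "")[[1]]
      mut <- runif(length(ch)) < mutation_rate
      ch[mut] <- sample(aa, sum(mut), replace = TRUE)
      paste(ch, collapse = "")
    }, character(1))
    names(query) <- if (n_genes) paste0("qry", seq_len(n_genes)) else character()
    decoys <- setNames(
      vapply(seq_len(n_decoys), function(i) rand_seq(), character(1)),
      if (n_decoys) paste0("decoy", seq_len(n_decoys)) else character())
    list(query = c(query, decoys), reference = reference,
         true_map = data.frame(
           query_gene = names(query), reference_gene = names(reference),
           stringsAsFactors = FALSE))
  })
}

#' Generate a random tiny stoichiometric system
#'
#' Small random LPs (at most `max_reactions` reactions) with bounded fluxes
#' and a single-reaction objective, feasible by construction (zero flux is
#' always admissible).  Used to verify the simplex backend against the
#' brute-force enumeration oracle [fba_enumerate_optimum()].
#'
#' @param seed RNG seed.
#' @param max_reactions maximum number of reactions.
#' @return a `stoich_system`.
#' @export
make_random_system <- function(seed, max_reactions = 6) {
  .with_seed(seed, function() {
    m <- sample(1:4, 1)
    n <- sample(2:max_reactions, 1)
    S <- matrix(sample(-2:2, m * n, replace = TRUE), m, n,
                dimnames = list(paste0("m", seq_len(m)),
                                paste0("r", seq_len(n))))
    lb <- setNames(ifelse(runif(n) < 0.4,
                          -sample(1:10, n, replace = TRUE), 0), colnames(S))
    ub <- setNames(as.numeric(sample(1:10, n, replace = TRUE)), colnames(S))
    obj <- setNames(numeric(n), colnames(S))
    obj[sample(n, 1)] <- 1
    structure(list(S = S, lb = lb, ub = ub, obj = obj,
                   b = setNames(numeric(m), rownames(S)),
                   row_ids = rownames(S), col_ids = colnames(S)),
              class = "stoich_system")
  })
}
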