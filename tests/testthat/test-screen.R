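report <- suppressWarnings(screen_interactions(milk_community))
groups <- auto_groups(milk_community)

test_that("the milk screen reproduces the narrated interaction verdicts", {
  rec <- report$records
  expect_true(all(rec$donor == "ST_C106_mini"))
  expect_true(all(rec$recipient == "LR_yoba_mini"))

  essential <- rec$metabolite[rec$essential]
  expect_setequal(essential, c("folate", "free_peptides"))

  # galactose transfer is real but individually dispensable: succinate and
  # glycerol can stand in as carbon sources
  gal <- rec[rec$metabolite == "galactose", ]
  expect_false(gal$essential)
  expect_gt(gal$transfer_flux, 0)
  expect_equal(gal$growth_after_knockout, 2.0, tolerance = 1e-9)

  # succinate and glycerol are secreted by the ST member at the pFBA optimum
  pf <- report$pfba_fluxes
  expect_gt(pf[["ST_C106_mini__SUCCtx"]], 0)
  expect_gt(pf[["ST_C106_mini__GLYCtx"]], 0)

  # all six reported compounds point the same way
  expect_setequal(unique(rec$compound_name),
                  c("Folic acid", "Galactose", "Glycerol", "Peptides",
                    "Succinate", "Xanthine/Guanine"))
})

test_that("essentiality is exactly growth abolition under an independent re-solve", {
  rec <- report$records
  for (i in seq_len(nrow(rec))) {
    cols <- crossfeedr:::.member_transports(milk_community, rec$metabolite[i],
                                            rec$recipient[i])
    sol <- solve_fba(knockout(milk_community$system, cols))
    mu <- if (sol$status == "optimal") sol$objective_value else 0
    expect_identical(rec$essential[i], mu < 1e-6)
    expect_equal(rec$growth_after_knockout[i], mu, tolerance = 1e-9)
  }
})

test_that("robust transfers balance donor secretion against recipient uptake", {
  rec <- report$records
  pf <- report$pfba_fluxes
  secr_cols <- c(folate = "FOLtx", free_peptides = NA, galactose = "GALtx",
                 glycerol = "GLYCtx", guanine = "GUAtx",
                 succinate = "SUCCtx", xanthine = "XANtx")
  for (i in seq_len(nrow(rec))) {
    expect_gte(rec$transfer_flux[i] * (rec$direction_robust[i]), -1e-9)
    b <- rec$metabolite[i]
    if (is.na(secr_cols[[b]])) next
    secreted <- pf[[paste0("ST_C106_mini__", secr_cols[[b]])]]
    exported <- pf[[paste0("EX_", b, "_e")]]
    # shared-pool balance: donor secretion = recipient uptake + system export
    expect_equal(secreted, rec$transfer_flux[i] + exported, tolerance = 1e-6)
  }
})

test_that("group knockouts expose the purine and carbon-source redundancy groups", {
  res <- screen_groups(milk_community,
                       list(c("xanthine", "guanine"),
                            c("galactose", "succinate", "glycerol"),
                            c("galactose", "succinate"),
                            character()))
  expect_true(res$jointly_essential[1])
  expect_true(res$jointly_essential[2])
  expect_false(res$jointly_essential[3])    # glycerol still feeds carbon
  expect_equal(res$growth[3], 1.0, tolerance = 1e-9)
  expect_equal(res$growth[4], report$baseline_growth, tolerance = 1e-9)
  expect_error(screen_groups(milk_community, list("unobtainium")),
               "not a shared metabolite")
})

test_that("auto_groups discovers exactly the two minimal redundancy groups", {
  expect_length(groups, 2)
  expect_setequal(groups[[1]], c("guanine", "xanthine"))
  expect_setequal(groups[[2]], c("galactose", "glycerol", "succinate"))
})

test_that("auto_groups is empty when every transfer is individually essential", {
  pair <- make_toy_pair(generator_config(n_essential = 2,
                                         n_redundant_paths = 0,
                                         n_extra_metabolites = 0, seed = 5))
  comm <- build_community(pair$a, pair$b, pair$medium)
  expect_length(auto_groups(comm), 0)
})

test_that("knockouts of non-shared transporters leave the record set unchanged", {
  # glucose and free amino acid uptake are idle, non-shared routes on milk
  sys_ko <- knockout(milk_community$system,
                     c("LR_yoba_mini__GLCt", "LR_yoba_mini__AAt"))
  comm2 <- milk_community
  comm2$system <- sys_ko
  rep2 <- suppressWarnings(screen_interactions(comm2))
  expect_identical(rep2$records$metabolite, report$records$metabolite)
  expect_identical(rep2$records$essential, report$records$essential)
})

test_that("the interaction table is sorted, complete and round-trips", {
  tab <- interaction_table(report, groups)
  expect_identical(names(tab), c("compound", "provides", "consumes",
                                 "essential", "robust", "flux", "group"))
  expect_true(all(tab$provides == "ST_C106_mini"))
  expect_true(all(tab$consumes == "LR_yoba_mini"))
  # essential block first, then descending flux
  expect_true(all(diff(tab$essential) <= 0))
  ness <- tab[!tab$essential, ]
  expect_true(all(diff(ness$flux) <= 1e-12))
  expect_identical(tab$group[tab$compound == "Galactose"],
                   "galactose+glycerol+succinate")

  path <- withr::local_tempfile(fileext = ".tsv")
  write_interaction_table(tab, path)
  expect_equal(read_interaction_table(path), tab, ignore_attr = TRUE,
               tolerance = 1e-9)

  empty <- report
  empty$records <- report$records[0, ]
  etab <- interaction_table(empty)
  expect_equal(nrow(etab), 0)
  write_interaction_table(etab, path)
  expect_equal(nrow(read_interaction_table(path)), 0)
})

test_that("a community with no shared metabolites screens to an empty record set", {
  a <- make_chain_model("LONE_A", uptake = 10)
  b <- make_chain_model("LONE_B", uptake = 10)
  comm <- build_community(a, b, medium(c(substrate = 10)))
  rep0 <- screen_interactions(comm)
  expect_equal(nrow(rep0$records), 0)
  expect_equal(rep0$baseline_growth, 5)
})

test_that("planted interactions are recovered exactly on generated pairs", {
  for (seed in c(1, 2, 3, 7)) {
    pair <- make_toy_pair(generator_config(n_essential = 2,
                                           n_redundant_paths = 2,
                                           n_extra_metabolites = 1,
                                           noise_reactions = 2, seed = seed))
    comm <- build_community(pair$a, pair$b, pair$medium)
    rep <- suppressWarnings(screen_interactions(comm))
    got_ess <- sort(rep$records$metabolite[rep$records$essential])
    expect_identical(got_ess, sort(pair$truth$essential_transfers$metabolite))
    got_groups <- auto_groups(comm)
    expect_setequal(vapply(got_groups, function(g) paste(sort(g), collapse = "+"),
                           character(1)),
                    vapply(pair$truth$or_groups, paste, collapse = "+",
                           FUN.VALUE = character(1)))
    inactive <- rep$records$metabolite[!rep$records$active]
    expect_true(all(pair$truth$inactive_shared %in% inactive))
  }
})
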