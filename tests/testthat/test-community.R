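test_that("two identical members split a shared bottleneck equally", {
  a <- make_chain_model("TWIN_A", uptake = 10)
  b <- make_chain_model("TWIN_B", uptake = 10)
  comm <- build_community(a, b, medium(c(substrate = 10)))
  sol <- solve_fba(comm$system)
  expect_valid_solution(comm$system, sol)
  expect_equal(sol$objective_value, 5)
  expect_equal(unname(sol$fluxes[comm$biomass_cols[1]]),
               unname(sol$fluxes[comm$biomass_cols[2]]), tolerance = 1e-9)
})

test_that("growth coupling forces joint failure when one member cannot grow", {
  a <- make_chain_model("GROWS", uptake = 10)
  b <- make_chain_model("STUCK", uptake = 10)
  b$reactions$upper_bound[b$reactions$id == "BIO"] <- 0
  comm <- build_community(a, b, medium(c(substrate = 10)))
  expect_equal(solve_fba(comm$system)$objective_value, 0)
})

test_that("the milk community grows at the bottleneck closed form with tight coupling", {
  sol <- solve_fba(milk_community$system)
  expect_valid_solution(milk_community$system, sol)
  expect_equal(sol$objective_value, MU_COMMUNITY, tolerance = 1e-9)
  gap <- abs(sol$fluxes[[milk_community$biomass_cols[1]]] -
             sol$fluxes[[milk_community$biomass_cols[2]]])
  expect_lte(gap, 1e-6)
  # coupled growth cannot beat the uncoupled merged system
  unc <- milk_community$system
  unc$S <- unc$S[rownames(unc$S) != "coupling", , drop = FALSE]
  unc$b <- unc$b[names(unc$b) != "coupling"]
  unc$row_ids <- setdiff(unc$row_ids, "coupling")
  expect_lte(sol$objective_value,
             solve_fba(unc)$objective_value + 1e-9)
})

test_that("mono-culture growth matches the narrated milk phenotypes", {
  expect_equal(suppressWarnings(mono_growth(milk$st, milk$medium)),
               MU_ST_MONO, tolerance = 1e-9)
  expect_equal(suppressWarnings(mono_growth(milk$lr, milk$medium)), 0)
  # enrichment with a sugar, amino acids, folate and a purine rescues the
  # auxotroph (the yeast-extract-style supplementation)
  enriched <- medium(c(milk$medium$uptake_bounds, glucose = 10,
                       amino_acids = 10, folate = 10, guanine = 10),
                     name = "enriched milk")
  expect_gt(suppressWarnings(mono_growth(milk$lr, enriched)), 0)
})

test_that("shared metabolites require a producer on one side and a transporter on the other", {
  expect_true(all(c("folate", "free_peptides", "galactose", "glycerol",
                    "guanine", "succinate", "xanthine") %in%
                    milk_community$shared_metabolites$base_id))
  expect_true(all(milk_community$shared_metabolites$donor == "ST_C106_mini"))
  expect_true(all(milk_community$shared_metabolites$recipient ==
                    "LR_yoba_mini"))
  # lactose and the raw milk peptides are consumed by ST only: not shared
  expect_false(any(c("lactose", "milk_peptides", "water") %in%
                     milk_community$shared_metabolites$base_id))

  # disjoint transporter sets: nothing shared
  a <- make_chain_model("ONLY_A", uptake = 10)
  b <- make_chain_model("ONLY_B", uptake = 10)
  b$metabolites$id <- sub("substrate", "other", b$metabolites$id)
  b$metabolites$name <- sub("substrate", "other", b$metabolites$name)
  names(b$stoichiometry) <- c("EX_other_e", "SUBt", "BIO")
  b$reactions$id <- names(b$stoichiometry)
  b$stoichiometry <- lapply(b$stoichiometry, function(st) {
    names(st) <- sub("substrate", "other", names(st)); st })
  b$objective_reaction_id <- "BIO"
  comm <- build_community(a, b, medium(c(substrate = 10, other = 10)))
  expect_equal(nrow(comm$shared_metabolites), 0)

  # symmetric members that can both secrete and absorb list both directions
  mk_sym <- function(id) {
    m <- make_chain_model(id, uptake = 10)
    m <- add_metabolite(m, "waste_e", "e", "waste")
    m <- add_metabolite(m, "waste_c", "c", "waste")
    m <- add_reaction(m, "WASTEt", c(waste_c = -1, waste_e = 1), -1000, 1000,
                      kind = "transport")
    m <- add_reaction(m, "WASTE_USE", c(substrate_c = -1, waste_c = 1),
                      -1000, 1000, kind = "internal")
    m <- add_reaction(m, "EX_waste_e", c(waste_e = -1), 0, 1000,
                      kind = "exchange")
    assert_valid_model(m)
  }
  sym <- build_community(mk_sym("SYM_A"), mk_sym("SYM_B"),
                         medium(c(substrate = 10)))
  waste <- sym$shared_metabolites[sym$shared_metabolites$base_id == "waste", ]
  expect_equal(nrow(waste), 2)
  expect_setequal(waste$donor, c("SYM_A", "SYM_B"))
})

test_that("steady state balances the shared extracellular pool", {
  sol <- solve_fba(milk_community$system)
  sys <- milk_community$system
  shared_rows <- grepl("_e$", rownames(sys$S))
  imbalance <- sys$S[shared_rows, , drop = FALSE] %*% sol$fluxes[sys$col_ids]
  expect_lt(max(abs(imbalance)), 1e-6)
})

test_that("community construction rejects members without biomass or identical ids", {
  a <- make_chain_model("SAME")
  expect_error(build_community(a, make_chain_model("SAME"),
                               medium(c(substrate = 10))), "distinct ids")
  nob <- make_chain_model("NOBIO")
  nob$objective_reaction_id <- NA_character_
  nob$reactions$kind[nob$reactions$id == "BIO"] <- "internal"
  expect_error(build_community(make_chain_model("OK"), nob,
                               medium(c(substrate = 10))), "biomass")
})
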