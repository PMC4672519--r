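test_that("a minimal JSON model reads with an inferred exchange reaction", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{
    "id": "MINI", "compartments": ["e"],
    "metabolites": [{"id": "glc_e", "name": "glucose", "compartment": "e"}],
    "reactions": [{"id": "EX_glc_e", "stoichiometry": {"glc_e": -1},
                   "lower_bound": -10, "upper_bound": 1000}]
  }', path)
  m <- read_model(path)
  expect_equal(nrow(m$metabolites), 1)
  expect_equal(nrow(m$reactions), 1)
  expect_identical(m$reactions$kind, "exchange")
})

test_that("models round-trip through both dialects", {
  for (model in list(milk$st, milk$lr)) {
    for (ext in c(".json", ".xml")) {
      path <- withr::local_tempfile(fileext = ext)
      write_model(model, path)
      expect_true(models_equal(read_model(path), model))
    }
  }
})

test_that("unicode names survive a round-trip", {
  m <- make_chain_model()
  m$metabolites$name[1] <- "substraté β"
  for (ext in c(".json", ".xml")) {
    path <- withr::local_tempfile(fileext = ext)
    write_model(m, path)
    back <- read_model(path)
    expect_identical(back$metabolites$name[back$metabolites$id == "substrate_e"],
                     "substraté β")
  }
})

test_that("the packaged ST fixture has biomass objective, lactose transport and a protease", {
  path <- system.file("extdata", "milk_consortium_mini", "ST.json",
                      package = "crossfeedr")
  m <- read_model(path)
  expect_identical(m$reactions$kind[m$reactions$id == m$objective_reaction_id],
                   "biomass")
  expect_true("LCTSt" %in% m$reactions$id)        # lactose transporter
  expect_true("PRTS" %in% m$reactions$id)         # casein protease
  expect_true(models_equal(m, milk$st))           # files track the generator
  expect_true(models_equal(
    read_model(system.file("extdata", "milk_consortium_mini", "LR.json",
                           package = "crossfeedr")), milk$lr))
})

test_that("validation reports one diagnostic per violated invariant", {
  m <- make_chain_model()
  expect_length(validate_model(m), 0)
  # violate three distinct invariants: duplicate metabolite id, bad bounds,
  # unknown stoichiometry key
  m$metabolites <- rbind(m$metabolites, m$metabolites[1, ])
  m$reactions$lower_bound[2] <- 5
  m$reactions$upper_bound[2] <- -5
  m$stoichiometry[["BIO"]] <- c(ghost_c = -1)
  expect_length(validate_model(m), 3)
  expect_error(assert_valid_model(m), "duplicate metabolite")
})

test_that("gene rules in files must reference declared genes", {
  m <- make_chain_model()
  m$reactions$gene_rule[m$reactions$id == "SUBt"] <- "gA and gB"
  expect_match(validate_model(m), "undeclared gene")
  m$genes <- c("gA", "gB")
  expect_length(validate_model(m), 0)
})

test_that("the packaged milk medium has the ten expected components", {
  med <- read_medium(system.file("extdata", "milk_consortium_mini",
                                 "milk.tsv", package = "crossfeedr"))
  expect_length(med$uptake_bounds, 10)
  expect_setequal(names(med$uptake_bounds),
                  c("biotin", "lactose", "milk_peptides", "nicotinate",
                    "pantothenate", "phosphate", "pyridoxamine", "riboflavin",
                    "thiamin", "water"))
})

test_that("medium reading handles empty tables, zero bounds and rejects bad rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("metabolite\tmax_uptake", path)
  expect_length(read_medium(path)$uptake_bounds, 0)

  writeLines(c("metabolite\tmax_uptake", "glc\t0"), path)
  med <- read_medium(path)
  expect_identical(unname(med$uptake_bounds["glc"]), 0)  # present but closed

  writeLines(c("metabolite\tmax_uptake", "glc\t-1"), path)
  expect_error(read_medium(path), "negative")

  writeLines(c("metabolite\tmax_uptake", "glc\t5", "glc\t7"), path)
  expect_error(read_medium(path), "duplicate")
})

test_that("reading a missing or malformed file gives a format error", {
  expect_error(read_model("/nonexistent/model.json"), "not found")
  path <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", path)
  expect_error(read_model(path), "parse failure")
  writeLines('{"id": "X"}', path)
  expect_error(read_model(path), "required field")
})
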