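test_that("the stoichiometric matrix of a small model has the hand-checked layout", {
  m <- make_chain_model(uptake = 10)
  sys <- build_system(m)
  expect_equal(dim(sys$S), c(2, 3))
  expect_equal(sys$S["substrate_e", "EX_substrate_e"], -1)
  expect_equal(sys$S["substrate_e", "SUBt"], -1)
  expect_equal(sys$S["substrate_c", "SUBt"], 1)
  expect_equal(sys$S["substrate_c", "BIO"], -1)
  expect_equal(unname(sys$obj["BIO"]), 1)
})

test_that("medium application opens exactly the listed exchanges", {
  sys <- build_system(milk$st, milk$medium)
  open <- names(sys$lb)[grepl("^EX_", names(sys$lb)) & sys$lb < 0]
  expect_length(open, 10)

  closed <- build_system(milk$st, medium(setNames(numeric(0), character(0)),
                                         "empty"))
  expect_true(all(closed$lb[grepl("^EX_", names(closed$lb))] == 0))

  expect_warning(
    build_system(make_chain_model(), medium(c(unobtainium = 5))),
    "no exchange reaction")
})

test_that("FBA solves the chain bottleneck and a closed medium means no growth", {
  sys <- build_system(make_chain_model(uptake = 10))
  sol <- solve_fba(sys)
  expect_valid_solution(sys, sol)
  expect_equal(sol$objective_value, 10)

  dark <- build_system(make_chain_model(uptake = 0))
  expect_equal(solve_fba(dark)$objective_value, 0)
})

test_that("FBA matches the brute-force enumeration oracle on 20 seeded tiny systems", {
  for (seed in 1:20) {
    sys <- make_random_system(seed)
    want <- fba_enumerate_optimum(sys)
    got <- solve_fba(sys)
    expect_true(want$feasible)   # zero flux is always admissible here
    expect_valid_solution(sys, got)
    expect_equal(got$objective_value, want$objective, tolerance = 1e-6)
  }
})

test_that("pFBA keeps the optimum and removes redundant parallel flux", {
  chain <- build_system(make_chain_model(uptake = 10))
  # unique optimum: pFBA reproduces the FBA solution up to its 1e-6
  # optimality slack
  expect_equal(solve_pfba(chain)$fluxes, solve_fba(chain)$fluxes,
               tolerance = 1e-5)

  par <- build_system(make_parallel_model(uptake = 10))
  fba_opt <- solve_fba(par)$objective_value
  pf <- solve_pfba(par)
  expect_valid_solution(par, pf)
  expect_equal(pf$objective_value, fba_opt, tolerance = 1e-6 * fba_opt)
  # minimal total |flux| is four reaction steps per unit of growth (the
  # single-path routing; no surplus circulation between the two paths)
  expect_equal(sum(abs(pf$fluxes)), 4 * pf$objective_value,
               tolerance = 1e-9)

  # a closed 2-cycle can carry arbitrary flux without touching the optimum;
  # pFBA must leave it empty
  m <- make_chain_model(uptake = 10)
  m <- add_metabolite(m, "a_c", "c", "a")
  m <- add_metabolite(m, "b_c", "c", "b")
  m <- add_reaction(m, "CYC1", c(a_c = -1, b_c = 1), 0, 1000,
                    kind = "internal")
  m <- add_reaction(m, "CYC2", c(b_c = -1, a_c = 1), 0, 1000,
                    kind = "internal")
  cyc <- build_system(assert_valid_model(m))
  pfc <- solve_pfba(cyc)
  expect_equal(unname(pfc$fluxes[c("CYC1", "CYC2")]), c(0, 0),
               tolerance = 1e-9)
})

test_that("FVA pins fully-determined reactions and spans parallel paths", {
  chain <- build_system(make_chain_model(uptake = 10))
  res <- fva(chain, fraction_of_optimum = 1.0)
  expect_equal(res$min_flux, c(-10, 10, 10), tolerance = 1e-6)
  expect_equal(res$max_flux, c(-10, 10, 10), tolerance = 1e-6)

  closed <- build_system(make_chain_model(uptake = 0))
  res0 <- fva(closed, fraction_of_optimum = 0)
  expect_true(all(abs(res0$min_flux) < 1e-6 & abs(res0$max_flux) < 1e-6))

  par <- build_system(make_parallel_model(uptake = 10))
  rp <- fva(par, c("PATH1", "PATH2"), fraction_of_optimum = 1.0)
  expect_equal(rp$min_flux, c(0, 0), tolerance = 1e-6)
  expect_equal(rp$max_flux, c(10, 10), tolerance = 1e-6)
})

test_that("knockouts zero the targeted reactions and never help the objective", {
  chain <- build_system(make_chain_model(uptake = 10))
  expect_equal(solve_fba(knockout(chain, "SUBt"))$objective_value, 0)
  expect_equal(solve_fba(knockout(chain, character()))$objective_value, 10)
  expect_error(knockout(chain, "NOPE"), "unknown reaction")

  par <- build_system(make_parallel_model(uptake = 10))
  expect_equal(solve_fba(knockout(par, "PATH1"))$objective_value, 10)

  # monotonicity over random systems and random knockout sets
  for (seed in 1:10) {
    sys <- make_random_system(seed)
    base <- solve_fba(sys)$objective_value
    k <- ((seed * 7) %% length(sys$col_ids)) + 1
    ko <- solve_fba(knockout(sys, sys$col_ids[seq_len(k)]))
    after <- if (ko$status == "optimal") ko$objective_value else -Inf
    expect_lte(after, base + 1e-9)
  }
})

test_that("flux reports round-trip through TSV", {
  sys <- build_system(make_chain_model(uptake = 10))
  sol <- solve_fba(sys)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_flux_report(sys, sol, path)
  back <- read.delim(path)
  expect_equal(back$reaction, sys$col_ids)
  expect_equal(back$flux, unname(sol$fluxes), tolerance = 1e-9)
})
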