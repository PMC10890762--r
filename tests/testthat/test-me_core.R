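test_that("enzyme demand follows mu*v/keff with the s-to-h conversion", {
  ## the canonical fold change between a 0.01 and an 88.72 1/s kinetome
  expect_equal(enzyme_demand(1, 0.9, 0.01) / enzyme_demand(1, 0.9, 88.72),
               8872)
  expect_equal(enzyme_demand(0, 1, 10), 0)
  ## inverse proportionality in keff
  expect_equal(enzyme_demand(2, 0.5, 20), enzyme_demand(2, 0.5, 10) / 2)
  ## explicit unit harmonization: keff in 1/s, fluxes per hour
  expect_equal(enzyme_demand(3, 0.6, 2), 0.6 * 3 / (2 * 3600))
  expect_error(enzyme_demand(1, 1, 0), "positive")
  expect_error(enzyme_demand(1, 1, -5), "positive")
})

test_that("assembled LP is deterministic and structurally as counted", {
  m <- mini_model()
  cond <- stress_condition()
  lp1 <- assemble_lp(m, 0.5, cond)
  lp2 <- assemble_lp(m, 0.5, cond)
  expect_identical(lp1$mat, lp2$mat)
  expect_identical(lp1$rhs, lp2$rhs)
  ## independent count: one balance row per metabolite, one partition row
  ## per folding protein, one proteome budget row; one column per
  ## (reaction x catalyst alternative)
  n_rows <- nrow(m$metabolites) + sum(m$proteins$folding) + 1
  n_cols <- sum(vapply(m$reactions, function(r)
    max(1L, length(r$catalysts)), 1L))
  expect_equal(nrow(lp1$mat), n_rows)
  expect_equal(ncol(lp1$mat), n_cols)

  ## the toy model, including catalyst alternatives and folding machinery
  toy <- toy_model()
  lp <- assemble_lp(toy, 0.5, cond)
  expect_equal(nrow(lp$mat),
               nrow(toy$metabolites) + sum(toy$proteins$folding) + 1)
  expect_equal(ncol(lp$mat), sum(vapply(toy$reactions, function(r)
    max(1L, length(r$catalysts)), 1L)))

  ## mu = 0 degenerates gracefully: zero flux is feasible
  lp0 <- assemble_lp(m, 0, cond)
  s0 <- solve_lp(numeric(ncol(lp0$mat)), lp0$mat, lp0$dir, lp0$rhs,
                 lp0$lb, lp0$ub, feasibility_only = TRUE)
  expect_equal(s0$status, "optimal")
})

test_that("unknown keff for a catalyzed reaction is a model error", {
  m <- mini_model()
  m <- add_reaction(m, "ORPHAN", "metabolic", stoich = c(s_c = -1),
                    catalysts = "E1")
  expect_error(assemble_lp(m, 0.1, stress_condition()), "keff")
})

test_that("bisection growth maximum matches the grid-scan oracle", {
  m <- mini_model()
  cond <- stress_condition()
  sol <- maximize_growth(m, cond, tol = 1e-5)
  gs <- grid_scan_mu(m, cond, mu_hi = 3, step = 2e-3)
  expect_lt(abs(sol$mu - gs$sup), 2e-3 + 2e-5)
  ## monotone feasibility across the scan validates the bisection premise
  expect_true(all(diff(gs$pattern) <= 0))
})

test_that("closing all uptake pins growth to zero and the proteome budget
           responds to the unmodeled fraction", {
  m <- mini_model()
  cond <- stress_condition()
  m0 <- m
  m0$reactions[["EX_s"]]$lb <- 0
  s0 <- maximize_growth(m0, cond, tol = 1e-5)
  expect_equal(s0$status, "optimal")
  expect_lt(s0$mu, 1e-4)
  ## the budget is an equality: a smaller unmodeled fraction demands more
  ## modeled synthesis per unit growth, so growth cannot rise
  mu_base <- maximize_growth(m, cond, tol = 1e-5)$mu
  m_tight <- m
  m_tight$params$unmodeled_protein_fraction <- 0
  mu_tight <- maximize_growth(m_tight, cond, tol = 1e-5)$mu
  expect_lte(mu_tight, mu_base + 2e-5)
})

test_that("infeasibility at mu = 0 returns a flagged solution, not an error", {
  m <- mini_model()
  ## force impossible demand at any growth rate
  m <- add_reaction(m, "DRAIN", "sink", stoich = c(prec_c = -1),
                    lb = 50, ub = 50)
  s <- maximize_growth(m, stress_condition(), tol = 1e-4)
  expect_equal(s$status, "infeasible")
  expect_true(is.na(s$mu))
})

test_that("fixed-growth optimization reproduces the optimum and handles
           blocked reactions", {
  m <- mini_model()
  cond <- stress_condition()
  sol <- maximize_growth(m, cond, tol = 1e-5)
  ## biomass objective at mu* equals mu*
  b <- fix_growth_and_optimize(m, cond, sol$mu - 1e-5, "GROWTH", "max")
  expect_equal(b$objective_value, sol$mu - 1e-5, tolerance = 1e-9)
  ## a blocked reaction ranges to exactly zero either way
  toy <- toy_model()
  sol_t <- toy_solve()
  lo <- fix_growth_and_optimize(toy, cond, 0.9 * sol_t$mu, "DEADRX", "min")
  hi <- fix_growth_and_optimize(toy, cond, 0.9 * sol_t$mu, "DEADRX", "max")
  expect_equal(lo$objective_value, 0)
  expect_equal(hi$objective_value, 0)
  ## max of a flux equals the sign-flipped min of its negation (solved by
  ## swapping the sense)
  hi2 <- fix_growth_and_optimize(m, cond, 0.8 * sol$mu, "EX_s", "max")
  lo2 <- fix_growth_and_optimize(m, cond, 0.8 * sol$mu, "EX_s", "min")
  expect_lte(lo2$objective_value, hi2$objective_value + 1e-8)
  ## infeasible fixed growth is flagged
  bad <- fix_growth_and_optimize(m, cond, 10, "EX_s", "max")
  expect_equal(bad$status, "infeasible")
})

test_that("gene knockouts bound translation and compose order-free", {
  toy <- toy_model()
  expect_error(knockout_gene(toy, "nosuchgene"), "unknown gene")
  ko1 <- knockout_gene(knockout_gene(toy, "ackA"), "luxS")
  ko2 <- knockout_gene(knockout_gene(toy, "luxS"), "ackA")
  expect_identical(ko1, ko2)
  expect_equal(ko1$reactions[["TR_ackA"]]$ub, 0)
  ## the original model is untouched
  expect_gt(toy$reactions[["TR_ackA"]]$ub, 0)
})

test_that("knocking out the sole catalyst of an essential step kills growth", {
  toy <- knockout_gene(toy_model(), "dxr")
  s <- maximize_growth(toy, stress_condition(), tol = 1e-4)
  ## growth (and the orphaned flux) collapse to the solver's
  ## feasibility-tolerance level
  expect_lt(s$mu, 0.01)
  expect_lt(abs(unname(s$flux["DXPR"])), 1e-3)
})

test_that("coupling constraints enumerate catalyzed reactions with positive
           keffs", {
  cc <- coupling_constraints(toy_model())
  expect_true(all(cc$keff > 0))
  expect_true("DXPR" %in% cc$reaction)
  ## alternative catalysts appear as separate rows
  expect_equal(sum(cc$reaction == "ACK"), 2)
  ## folding-pathway reactions are coupled via pathway rates, not the vector
  expect_false(any(grepl("^FOLD_", cc$reaction)))
})
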