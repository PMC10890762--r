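test_that("FVA nests across growth fractions and matches vertex
           enumeration on the reduced model", {
  m <- mini_model()
  cond <- stress_condition()
  sol <- maximize_growth(m, cond, tol = 1e-5)
  fv <- fva(m, cond, c(0.95, 1), c("EX_s", "GROWTH"), solution = sol,
            tol = 1e-5)
  ## biomass at full growth collapses to mu* (within the bisection backoff)
  g1 <- fv[fv$reaction == "GROWTH" & fv$fraction == 1, ]
  expect_equal(g1$min, g1$max, tolerance = 1e-6)
  expect_equal(g1$min, sol$mu, tolerance = 1e-3)
  ## (range nesting across fractions is exercised on the toy model, whose
  ## overflow branch gives the fluxes genuine ranges; this chain model is
  ## fully determined at fixed growth)
  ## brute-force vertex oracle at 95% growth
  lp <- assemble_lp(m, 0.95 * sol$mu, cond)
  ve <- enumerate_vertices(lp$mat, lp$rhs, lp$lb, lp$ub,
                           as.numeric(lp$cols$rxn == "EX_s"))
  r95 <- fv[fv$reaction == "EX_s" & fv$fraction == 0.95, ]
  expect_equal(unname(r95$min), unname(ve["min"]), tolerance = 1e-6)
  expect_equal(unname(r95$max), unname(ve["max"]), tolerance = 1e-6)
  ## uptake is negative under the secretion-positive convention
  expect_lt(r95$min, 0)
})

test_that("proteome mass fractions normalize correctly", {
  toy <- toy_model()
  sol <- toy_solve()
  rep <- proteome_mass_fractions(toy, sol)
  expect_equal(sum(rep$proteins$mass_fraction), 1, tolerance = 1e-9)
  expect_equal(rep$modeled_protein_fraction,
               1 - toy$params$unmodeled_protein_fraction,
               tolerance = 1e-3)
  ## fractions are invariant under uniform rescaling of molecular weights:
  ## masses are mw * v / mu, so scaling mw and rescaling the reported table
  ## by the same factor leaves fractions unchanged
  scaled <- toy
  scaled$proteins$mw_kda <- scaled$proteins$mw_kda * 3
  rep2 <- proteome_mass_fractions(scaled, sol)
  expect_equal(rep2$proteins$mass_fraction, rep$proteins$mass_fraction,
               tolerance = 1e-12)
})

test_that("category aggregation sums to one and respects annotations", {
  rep <- proteome_mass_fractions(toy_model(), toy_solve())
  agg <- category_aggregate(rep)
  expect_equal(sum(agg), 1, tolerance = 1e-9)
  ## single-category annotation puts everything in it
  ann <- stats::setNames(rep("all", nrow(rep$proteins)), rep$proteins$id)
  expect_equal(unname(category_aggregate(rep, ann)), 1, tolerance = 1e-9)
  ## permutation invariance
  shuffled <- rep
  idx <- rev(seq_len(nrow(rep$proteins)))
  shuffled$proteins <- rep$proteins[idx, ]
  expect_equal(sort(category_aggregate(shuffled)), sort(agg))
  ## unannotated proteins fall into 'unknown' with a warning
  ann2 <- ann[-1]
  expect_warning(agg2 <- category_aggregate(rep, ann2), "unknown")
  expect_true("unknown" %in% names(agg2))
})

test_that("chaperone category mass grows under thermal stress", {
  toy <- toy_model()
  lo <- category_aggregate(proteome_mass_fractions(
    toy, toy_solve(temp_c = 34, tol = 1e-4, keff = "heat_evolved")))
  hi <- category_aggregate(proteome_mass_fractions(
    toy, toy_solve(temp_c = 44, tol = 1e-4, keff = "heat_evolved")))
  expect_gt(hi["chaperone"], lo["chaperone"])
})

test_that("mass-balance reports pass at optima and expose perturbations", {
  toy <- toy_model()
  sol <- toy_solve()
  mb <- mass_balance_report(toy, sol)
  expect_true(attr(mb, "pass"))
  expect_lte(attr(mb, "max_residual"), 1e-6)
  ## manual perturbation of one flux shows up as the stoichiometric
  ## coefficient on the touched metabolites
  lp <- assemble_lp(toy, sol$mu, sol$condition)
  x <- unname(sol$flux_by_column[colnames(lp$mat)])
  x[which(colnames(lp$mat) == "GLYC")] <- x[which(colnames(lp$mat) ==
                                                    "GLYC")] + 1
  resid <- as.vector(lp$mat[lp$met_rows, ] %*% x)
  names(resid) <- lp$row_ids[lp$met_rows]
  expect_equal(unname(resid["glc_c"]), -1, tolerance = 1e-6)
  expect_equal(unname(resid["pyr_c"]), 2, tolerance = 1e-6)
  ## determinism across repeated solves
  again <- maximize_growth(toy, stress_condition(), tol = 1e-5)
  expect_identical(again$mass_balance_residuals,
                   sol$mass_balance_residuals)
})

test_that("condition grids enumerate the Cartesian product and reproduce
           byte-identical CSVs", {
  m <- mini_model()
  d1 <- file.path(tempdir(), "grid1"); d2 <- file.path(tempdir(), "grid2")
  g <- condition_grid(m, c(35, 37), 7, c(1, 10), out_dir = d1, tol = 1e-4)
  expect_equal(nrow(g$phenotypes), 4)
  expect_equal(length(unique(g$phenotypes$condition_id)), 4)
  g1 <- condition_grid(m, 37, 7, 1, out_dir = d2, tol = 1e-4)
  expect_equal(nrow(g1$phenotypes), 1)
  ## deterministic emission
  d3 <- file.path(tempdir(), "grid3")
  condition_grid(m, c(35, 37), 7, c(1, 10), out_dir = d3, tol = 1e-4)
  for (f in c("phenotypes.csv", "proteome.csv", "fluxome.csv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d3, f)))
  }
  ## schema of the phenotype file
  ph <- utils::read.csv(file.path(d1, "phenotypes.csv"))
  expect_true(all(c("condition_id", "temp_c", "ph", "ros_mult",
                    "keff_label", "mu_per_h") %in% names(ph)))
})

test_that("fluxome dumps carry the documented two-column schema", {
  path <- tempfile(fileext = ".csv")
  write_fluxome(toy_solve(), path)
  fx <- utils::read.csv(path)
  expect_equal(names(fx), c("reaction_id", "flux_mmol_gDW_h"))
  expect_true("GROWTH" %in% fx$reaction_id)
})
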