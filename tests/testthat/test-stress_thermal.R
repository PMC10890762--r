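spec_protein <- function(dHm = 500, cp = 8, tm = 318, compartment = "cytoplasm",
                         kf_ref = 5, agg = 0.5) {
  list(id = "x", mw_kda = 40, compartment = compartment, dHm_kj_mol = dHm,
       cp_kj_mol_k = cp, tm_k = tm, kf_ref = kf_ref, agg = agg)
}

test_that("Gibbs-Helmholtz unfolding free energy behaves at its anchors", {
  p <- spec_protein()
  ## zero at the melting temperature by construction
  expect_equal(delta_g_unfold(p, p$tm_k), 0, tolerance = 1e-12)
  ## with no heat-capacity term a positive melting enthalpy stabilizes below Tm
  p0 <- spec_protein(cp = 0)
  expect_gt(delta_g_unfold(p0, 310), 0)
  expect_lt(suppressWarnings(delta_g_unfold(p0, 325)), 0)
  ## frozen value from an independent evaluation of the closed form
  expect_equal(delta_g_unfold(spec_protein(500, 8, 318), 310),
               11.7667478986, tolerance = 1e-9)
  expect_warning(delta_g_unfold(p, 330), "validity window")
})

test_that("unfolding Keq is 1 at Tm and rises with temperature near it", {
  p <- spec_protein()
  expect_equal(unfolding_keq(p, p$tm_k), 1, tolerance = 1e-12)
  expect_equal(unfolding_keq(spec_protein(500, 8, 318), 310),
               1.0405070681e-02, tolerance = 1e-8)
  temps <- seq(p$tm_k - 10, p$tm_k + 5, by = 1)
  keqs <- suppressWarnings(vapply(temps, unfolding_keq, 0, protein = p))
  expect_true(all(diff(keqs) > 0))
})

test_that("folding network construction validates its inputs", {
  m <- mini_model()
  ## no chaperones registered yet
  expect_error(build_folding_network(m, "E1"), "chaperone")
  toy <- toy_model()
  expect_error(build_folding_network(toy, "dxr"), "already")
  expect_error(lon_degradation(toy, "pdhA"), "folding network")
})

test_that("chaperone mass fraction increases with heat", {
  frac_chap <- function(temp) {
    sol <- toy_solve(temp_c = temp, tol = 1e-4, keff = "heat_evolved")
    rep <- proteome_mass_fractions(toy_model(), sol)
    sum(rep$proteins$mass_fraction[rep$proteins$id %in% c("dnaK", "groL")])
  }
  lo <- frac_chap(37)
  hi <- frac_chap(44)
  expect_gt(hi, lo)
  expect_gt(hi, 0.02)
})

test_that("translation of a folding protein is conserved across routes", {
  ## translation flux = folding + spontaneous pool consumption +
  ## degradation + unfolded sink at any optimum
  sol <- toy_solve(temp_c = 42, tol = 1e-4)
  fb <- sol$flux_by_column
  for (pid in c("dxr", "aaS", "glyK")) {
    lhs <- fb[paste0("TR_", pid)]
    outs <- fb[grepl(paste0("^(FOLD_[a-zA-Z]+_|LON_|SINK_unfolded_)", pid,
                            "$"), names(fb))]
    ## spontaneous self-consumption is part of the unfolded balance; verify
    ## through the model residuals instead of re-deriving coefficients
    expect_gte(lhs + 1e-9, sum(outs))
  }
  expect_lte(max(abs(sol$mass_balance_residuals)), 1e-6)
})

test_that("Lon degradation recycles amino acids at an ATP cost", {
  toy <- toy_model()
  r <- toy$reactions[["LON_dxr"]]
  n_aa <- 60 / toy$params$aa_mw_kda
  ## full amino-acid recovery, split over the pools
  expect_equal(sum(r$stoich[toy$params$aa_pools]), n_aa, tolerance = 1e-9)
  expect_equal(unname(r$stoich["atp_c"]), -n_aa, tolerance = 1e-9)
  ## removing Lon weakly lowers growth (a relaxation in reverse)
  mu_with <- toy_solve(temp_c = 42, tol = 1e-4)$mu
  ko <- knockout_gene(toy, "lon")
  mu_without <- maximize_growth(ko, stress_condition(42, 7, 1),
                                tol = 1e-4)$mu
  expect_lte(mu_without, mu_with + 2e-4)
})
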