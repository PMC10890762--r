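test_that("consolidation overrides entries with provenance and is
           idempotent", {
  base <- keff_vector(c(DXPR = 0.01, RHCC = 0.01, GLYC = 4), "wild_type")
  ## empty overrides: identical values, new label
  same <- consolidate(base, label = "relabel")
  expect_equal(unclass(same)[names(base)], unclass(base)[names(base)],
               ignore_attr = TRUE)
  expect_equal(attr(same, "label"), "relabel")
  ## the canonical single-entry consolidation: 0.01 -> 88.72
  cons <- consolidate(base, c(DXPR = 88.72), "consolidated")
  expect_equal(unname(cons["DXPR"]), 88.72)
  expect_equal(sum(unclass(cons)[names(base)] !=
                     unclass(base)[names(base)]), 1)
  expect_match(attr(cons, "provenance"), "0.01 -> 88.72")
  ## idempotent
  cons2 <- consolidate(cons, c(DXPR = 88.72), "consolidated")
  expect_equal(unclass(cons2)[names(base)], unclass(cons)[names(base)])
  expect_error(consolidate(base, c(DXPR = -1)), "positive")
  expect_error(consolidate(base, c(NOPE = 1)), "unknown")
})

test_that("keff vectors round-trip through the TSV interface", {
  v <- toy_model()$keff_vectors$wild_type
  path <- tempfile(fileext = ".tsv")
  write_keff_tsv(v, path)
  back <- read_keff_tsv(path)
  expect_equal(as.numeric(back), as.numeric(v))
  expect_equal(names(back), names(v))
  ## header is mandatory
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("rxn\tvalue", "GLYC\t4"), bad)
  expect_error(read_keff_tsv(bad), "header")
})

test_that("the single-effect sensitivity screen ranks the terpenoid
           bottleneck first and leaves blocked reactions untouched", {
  m <- toy_model()
  scr <- sensitivity_screen(m, m$keff_vectors$wild_type,
                            m$keff_vectors$heat_evolved,
                            stress_condition(), tol = 1e-5)
  expect_equal(scr$reaction_id[1], "DXPR")
  expect_true(all(diff(abs(scr$delta)) <= 1e-12))
  expect_equal(scr$delta[scr$reaction_id == "DEADRX"], 0)
  expect_equal(scr$delta, scr$mu_swapped - scr$mu_base)
  ## identical vectors yield an empty screen
  empty <- sensitivity_screen(m, m$keff_vectors$wild_type,
                              m$keff_vectors$wild_type, stress_condition())
  expect_equal(nrow(empty), 0)
})

test_that("the screen restores the model exactly", {
  m <- toy_model()
  cond <- stress_condition()
  before <- maximize_growth(m, cond, tol = 1e-5)
  invisible(sensitivity_screen(m, m$keff_vectors$wild_type,
                               m$keff_vectors$heat_evolved, cond,
                               tol = 1e-4))
  after <- maximize_growth(m, cond, tol = 1e-5)
  expect_identical(before$mu, after$mu)
  expect_identical(before$flux, after$flux)
})

test_that("keff sweeps separate redundant from growth-critical reactions", {
  m <- toy_model()
  cond <- stress_condition()
  ## redundant recycling step: growth barely moves, catalyst cost swings
  pr <- redundancy_probe(m, "RHCC", c(0.01, 1, 28.8), cond, tol = 1e-5)
  expect_lt((max(pr$mu) - min(pr$mu)) / max(pr$mu), 0.01)
  expect_gt(max(pr$catalyst_mass_fraction) /
              min(pr$catalyst_mass_fraction), 10)
  ## essential bottleneck: growth strictly increases with keff
  pd <- redundancy_probe(m, "DXPR", c(0.01, 0.1, 1), cond, tol = 1e-5)
  expect_true(all(diff(pd$mu) > 0))
  ## single-point grid gives a single-row table
  one <- redundancy_probe(m, "RHCC", 0.01, cond, tol = 1e-4)
  expect_equal(nrow(one), 1)
  expect_error(redundancy_probe(m, "RHCC", c(-1, 2), cond), "positive")
  expect_error(redundancy_probe(m, "NOPE", 1, cond), "unknown")
})
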