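test_that("damage flux is first-order in ROS and in enzyme amount", {
  rule <- list(rate_per_nm_h = 6)
  expect_equal(damage_flux(rule, 2, ros_environment(multiplier = 0)), 0)
  d_lo <- damage_flux(rule, 1, ros_environment(multiplier = 0.01))
  d_hi <- damage_flux(rule, 1, ros_environment(multiplier = 10))
  expect_equal(d_hi / d_lo, 1000)
  expect_equal(damage_flux(rule, 3, ros_environment(multiplier = 1)),
               3 * damage_flux(rule, 1, ros_environment(multiplier = 1)))
})

test_that("iron-sulfur cycle: no repair without ROS, repair is worth having,
           iron is conserved", {
  sol0 <- toy_solve(ros = 0, tol = 1e-4)
  expect_equal(unname(sol0$flux["FESREP_nuoX"]), 0, tolerance = 1e-6)
  sol10 <- toy_solve(ros = 10, tol = 1e-4)
  ## blocking the repair route weakly lowers growth under heavy ROS
  blocked <- toy_model()
  blocked$reactions[["FESREP_nuoX"]]$ub <- 0
  mu_blocked <- maximize_growth(blocked, stress_condition(37, 7, 10),
                                tol = 1e-4)$mu
  expect_lte(mu_blocked, sol10$mu + 2e-4)
  ## the Fe(II) pool balances: what damage releases, repair/Fenton/Dps
  ## (plus the trace uptake) consume
  expect_lt(abs(sol10$mass_balance_residuals["fe2_c"]), 1e-6)
})

test_that("damage must be compensated by extra synthesis when repair is
           uneconomical", {
  ## the ilvD-like Fe-S enzyme has a deliberately expensive repair route, so
  ## ROS raises its mass fraction while growth falls
  rep1 <- proteome_mass_fractions(toy_model(), toy_solve(ros = 1, tol = 1e-4))
  rep10 <- proteome_mass_fractions(toy_model(),
                                   toy_solve(ros = 10, tol = 1e-4))
  mf <- function(r, id) r$proteins$mass_fraction[r$proteins$id == id]
  expect_gt(mf(rep10, "ilvD"), mf(rep1, "ilvD"))
  expect_lt(toy_solve(ros = 10, tol = 1e-4)$mu,
            toy_solve(ros = 1, tol = 1e-4)$mu)
})

test_that("Fenton chemistry and Dps sequestration respond to the iron pool", {
  ## AhpC detox is cheaper than DNA damage: Fenton stays off at baseline
  sol <- toy_solve(ros = 1, tol = 1e-4)
  expect_equal(unname(sol$flux["FENTON"]), 0, tolerance = 1e-9)
  ## Dps holds the surplus iron and grows with ROS
  rep1 <- proteome_mass_fractions(toy_model(), sol)
  rep10 <- proteome_mass_fractions(toy_model(),
                                   toy_solve(ros = 10, tol = 1e-4))
  mf <- function(r, id) r$proteins$mass_fraction[r$proteins$id == id]
  expect_gt(mf(rep10, "dps"), mf(rep1, "dps"))
})

test_that("mismetallation trades catalytic efficiency for ROS immunity", {
  toy <- toy_model()
  expect_error(mismetallation_variant(toy, "tcaA", "Mn2", 1.2), "0, 1")
  expect_error(mismetallation_variant(toy, "dxr"), "Fe\\(II\\)")
  ## at rest the Fe(II) holo form carries the cycle flux
  sol0 <- toy_solve(ros = 0, tol = 1e-4)
  expect_gt(unname(sol0$flux_by_column["TCA__tcaA"]), 0.1)
  expect_equal(unname(sol0$flux_by_column["TCA__tcaA_mn"]), 0)
  ## under oxidative stress the Mn variant takes over
  sol3 <- toy_solve(ros = 3, tol = 1e-4)
  expect_gt(unname(sol3$flux_by_column["TCA__tcaA_mn"]), 0.1)
})

test_that("the Fe-S-free respiratory bypass gains flux share under ROS", {
  share <- function(ros) {
    s <- toy_solve(ros = ros, tol = 1e-4)
    unname(s$flux["NDH"] / max(s$flux["NDH"] + s$flux["NUO"], 1e-12))
  }
  expect_equal(share(0.01), 0, tolerance = 1e-9)
  expect_gt(share(10), share(0.01))
})

test_that("amino-acid supplementation relieves ROS-damaged biosynthesis", {
  mu_none <- toy_solve(ros = 10, tol = 1e-4)$mu
  mu_full <- toy_solve(ros = 10, tol = 1e-4, aa = "full")$mu
  expect_gt(mu_full, mu_none)
  ## withholding the branched-chain pool forfeits part of the benefit
  mu_no_ilv <- toy_solve(ros = 10, tol = 1e-4, aa = "minus_ile_val")$mu
  expect_lte(mu_no_ilv, mu_full + 2e-4)
})
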