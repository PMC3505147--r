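test_that("marginal effect follows the truncated-mean form", {
  out <- ex_outcome(); scr <- ex_screening()
  # no truncation: lambda1 = beta1 + beta3 * mu_x
  expect_equal(marginal_effect(out, scr, -Inf), -0.2 - 0.25 * 5)
  # no interaction: lambda1 = beta1 at every threshold
  out0 <- outcome_model(beta1 = -0.2, beta3 = 0, sigma = 2.5)
  for (a in c(-Inf, 3, 5, 7)) expect_equal(marginal_effect(out0, scr, a), -0.2)
  # frozen via the truncated-mean oracle: -0.2 - 0.25 * E[X | X >= 5.3]
  expect_equal(marginal_effect(out, scr, 5.3), -1.8978828, tolerance = 1e-6)
  # same-sign coefficients: |lambda1| nondecreasing in a
  a_grid <- seq(-1, 11, by = 0.25)
  lam <- vapply(a_grid, function(a) marginal_effect(out, scr, a), 1)
  expect_true(all(diff(abs(lam)) >= 0))
})

test_that("coefficient solicitation inverts two targeted effects", {
  scr <- ex_screening()
  out <- ex_outcome()
  lam1 <- marginal_effect(out, scr, 4)
  lam2 <- marginal_effect(out, scr, 7)
  b <- solve_betas(4, lam1, 7, lam2, scr)
  expect_equal(unname(b["beta1"]), -0.2, tolerance = 1e-10)
  expect_equal(unname(b["beta3"]), -0.25, tolerance = 1e-10)
  # round trip: the recovered coefficients reproduce the targets to 1e-10
  out_b <- outcome_model(beta1 = b[["beta1"]], beta3 = b[["beta3"]], sigma = 2.5)
  expect_equal(marginal_effect(out_b, scr, 4), lam1, tolerance = 1e-10)
  expect_equal(marginal_effect(out_b, scr, 7), lam2, tolerance = 1e-10)
  # equal targets: no interaction
  b0 <- solve_betas(4, -1.5, 7, -1.5, scr)
  expect_equal(unname(b0["beta1"]), -1.5, tolerance = 1e-10)
  expect_equal(unname(b0["beta3"]), 0, tolerance = 1e-10)
  expect_error(solve_betas(5, -1, 5, -2, scr),
               class = "enrichcost_singular_solicitation")
})

test_that("power approximation is calibrated at the null and monotone in n", {
  scr <- ex_screening(); tst <- ex_test()
  out_null <- outcome_model(beta1 = 0, beta3 = 0, sigma = 2.5)
  expect_warning(
    p0 <- power_marginal(50, 5, out_null, scr, tst),
    class = "enrichcost_no_effect")
  expect_equal(p0, pnorm(-1.96), tolerance = 1e-12)
  out <- ex_outcome()
  ns <- c(5, 10, 20, 40, 80, 160)
  ps <- vapply(ns, function(n) power_marginal(n, 5.3, out, scr, tst), 1)
  expect_true(all(diff(ps) > 0))
  expect_gt(power_marginal(1e4, 5.3, out, scr, tst), 0.999999)
  # frozen direct evaluation at the worked example
  expect_equal(power_marginal(43, 5.3, out, scr, tst), 0.90318, tolerance = 1e-4)
})

test_that("required_n inverts the power formula exactly", {
  out <- ex_outcome(); scr <- ex_screening(); tst <- ex_test()
  expect_equal(required_n(5.3, out, scr, tst), 42.5177, tolerance = 1e-4)
  expect_equal(required_n(7, out, scr, tst), 29.5010, tolerance = 1e-4)
  # inversion consistency across the threshold range
  for (a in seq(5 - 2 * 2, 5 + 2 * 2, by = 0.5)) {
    n <- required_n(a, out, scr, tst)
    expect_equal(power_marginal(n, a, out, scr, tst), 0.90, tolerance = 1e-9)
  }
  # doubling |lambda1| at fixed variances quarters n*
  scr0 <- screening_model(mu_x = 5, sd_x = 2)  # rho irrelevant here
  o1 <- outcome_model(beta1 = -1, beta2 = 1, beta3 = 0, sigma = 2.5)
  o2 <- outcome_model(beta1 = -2, beta2 = 1, beta3 = 0, sigma = 2.5)
  expect_equal(required_n(5, o1, scr0, tst) / required_n(5, o2, scr0, tst),
               4, tolerance = 1e-10)
  out_null <- outcome_model(beta1 = 0, beta3 = 0, sigma = 2.5)
  expect_error(required_n(5, out_null, scr, tst),
               class = "enrichcost_unattainable_power")
})

test_that("unequal-allocation power reduces and interpolates correctly", {
  out <- ex_outcome(); scr <- ex_screening(); tst <- ex_test()
  expect_equal(power_unequal(43, 43, 5.3, out, scr, tst),
               power_marginal(43, 5.3, out, scr, tst), tolerance = 1e-12)
  p <- power_unequal(30, 60, 5.3, out, scr, tst)
  expect_gt(p, power_marginal(30, 5.3, out, scr, tst))
  expect_lt(p, power_marginal(60, 5.3, out, scr, tst))
  # one arm unbounded: its variance contribution vanishes
  v <- enrichcost:::arm_variances(out, scr, 5.3)
  lim <- pnorm(abs(marginal_effect(out, scr, 5.3)) /
                 sqrt(v[["control"]] / 30) - 1.96)
  expect_equal(power_unequal(30, 1e12, 5.3, out, scr, tst), lim,
               tolerance = 1e-6)
})

test_that("critical value flag switches between 1.96 and the exact quantile", {
  out <- ex_outcome(); scr <- ex_screening()
  t_print <- test_spec(use_z_critical = TRUE)
  t_exact <- test_spec(use_z_critical = FALSE)
  p1 <- power_marginal(43, 5.3, out, scr, t_print)
  p2 <- power_marginal(43, 5.3, out, scr, t_exact)
  expect_false(isTRUE(all.equal(p1, p2, tolerance = 1e-8)))
  expect_equal(p1, p2, tolerance = 1e-3)
})
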