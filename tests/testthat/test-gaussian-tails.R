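test_that("upper_tail matches closed forms and handles the no-truncation path", {
  expect_equal(upper_tail(5, 2, 5), 0.5)
  expect_equal(upper_tail(5, 2, -Inf), 1)
  # complementary-error-function value 0.5 * erfc(1/sqrt(2))
  expect_equal(upper_tail(5, 2, 7), 0.15865525, tolerance = 1e-7)
  a <- seq(-1, 11, length.out = 50)
  expect_true(all(diff(vapply(a, function(x) upper_tail(5, 2, x), 1)) <= 0))
  expect_error(upper_tail(5, 0, 3), class = "enrichcost_invalid_parameter")
})

test_that("truncated moments match closed forms at half-normal and no truncation", {
  expect_equal(trunc_mean(5, 2, -Inf), 5)
  expect_equal(trunc_mean(0, 1, 0), sqrt(2 / pi), tolerance = 1e-12)
  expect_equal(trunc_var(0, 1, -Inf), 1)
  expect_equal(trunc_var(0, 1, 0), 1 - 2 / pi, tolerance = 1e-12)
})

test_that("truncated moments agree with a seeded rejection-sampling oracle", {
  for (a in c(5 - 2 * 2, 5, 5 + 1.5 * 2, 5.3)) {
    xs <- mc_truncated(5, 2, a, n = 1e6)
    m <- length(xs)
    se_mean <- sd(xs) / sqrt(m)
    expect_lt(abs(trunc_mean(5, 2, a) - mean(xs)), 4 * se_mean)
    # SE of the sample variance ~ sqrt((mu4 - var^2)/m)
    se_var <- sqrt((mean((xs - mean(xs))^4) - var(xs)^2) / m)
    expect_lt(abs(trunc_var(5, 2, a) - var(xs)), 4 * se_var)
  }
})

test_that("truncated moments are monotone in the threshold", {
  a_grid <- seq(5 - 3 * 2, 5 + 3 * 2, length.out = 100)
  means <- vapply(a_grid, function(a) trunc_mean(5, 2, a), 1)
  vars <- vapply(a_grid, function(a) trunc_var(5, 2, a), 1)
  expect_true(all(diff(means) >= 0))
  expect_true(all(diff(vars) <= 0))
  expect_true(all(means >= pmax(5, a_grid)))
  expect_true(all(vars > 0 & vars <= 4))
})

test_that("degenerate truncation is refused", {
  expect_error(trunc_mean(0, 1, 9), class = "enrichcost_degenerate_truncation")
  expect_error(trunc_var(0, 1, 9), class = "enrichcost_degenerate_truncation")
})

test_that("bivariate upper rectangle matches independence, orthant and quadrature oracles", {
  # independence factorization
  expect_equal(bvn_upper_rect(0.4, -0.3, 0),
               pnorm(0.4, lower.tail = FALSE) * pnorm(-0.3, lower.tail = FALSE),
               tolerance = 1e-12)
  # orthant closed form P(U>=0, V>=0) = 1/4 + asin(rho)/(2 pi)
  for (rho in c(-0.5, 0.3, 0.7, 0.95))
    expect_equal(bvn_upper_rect(0, 0, rho), 0.25 + asin(rho) / (2 * pi),
                 tolerance = 1e-10)
  # frozen value verified against an independent CDF implementation and a
  # 10^7-draw Monte Carlo
  expect_equal(bvn_upper_rect(0.4, 0, 0.7), 0.28385271, tolerance = 1e-7)
  # symmetry in (u, v)
  expect_equal(bvn_upper_rect(0.8, -0.2, 0.6), bvn_upper_rect(-0.2, 0.8, 0.6),
               tolerance = 1e-10)
  # infinite limits reduce to univariate tails
  expect_equal(bvn_upper_rect(-Inf, 0.7, 0.5),
               pnorm(0.7, lower.tail = FALSE))
  expect_equal(bvn_upper_rect(-Inf, -Inf, 0.5), 1)
  expect_error(bvn_upper_rect(0, 0, 1), class = "enrichcost_invalid_parameter")
})

test_that("bivariate rectangle satisfies inclusion-exclusion", {
  for (rho in c(-0.7, 0.2, 0.7)) {
    for (uv in list(c(0.4, 0), c(-1, 0.5), c(1.2, 1.2))) {
      u <- uv[1]; v <- uv[2]
      # P(U>=u, V>=v) = P(U>=u) + P(V>=v) - 1 + P(U<u, V<v), and
      # P(U<u, V<v) = P(-U>=-u, -V>=-v) with the same rho
      lhs <- bvn_upper_rect(u, v, rho)
      rhs <- pnorm(u, lower.tail = FALSE) + pnorm(v, lower.tail = FALSE) -
        1 + bvn_upper_rect(-u, -v, rho)
      expect_equal(lhs, rhs, tolerance = 1e-8)
    }
  }
})

test_that("conditional pass probability reduces correctly and matches the oracle ratio", {
  sm <- ex_screening(rho = 0.7)
  expect_equal(cond_upper(sm, 5.8, -Inf), upper_tail(5, 2, 5.8))
  sm0 <- ex_screening(rho = 0)
  expect_equal(cond_upper(sm0, 5.8, 4.2), upper_tail(5, 2, 5.8),
               tolerance = 1e-12)
  # frozen ratio of the two verified oracles: 0.28385271 / 0.5
  expect_equal(cond_upper(sm, 5.8, 5), 0.56770541, tolerance = 1e-6)
  # nondecreasing in b when rho > 0
  bs <- seq(2, 8, by = 0.5)
  ps <- vapply(bs, function(b) cond_upper(sm, 5.8, b), 1)
  expect_true(all(diff(ps) >= 0))
  expect_error(cond_upper(sm, 5, 5 + 2 * 9),
               class = "enrichcost_degenerate_truncation")
})
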