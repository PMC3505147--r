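test_that("two-stage cost reduces to one-stage when the prescreen filters nobody", {
  out <- ex_outcome(); scr <- ex_screening(); tst <- ex_test()
  cst <- ex_costs()  # c_pre + c_scr = c_rec = 300
  for (a in c(4, 5.3, 6.5)) {
    one <- evaluate_onestage(a, out, scr, cst, tst)
    expect_equal(total_cost_twostage(a, -Inf, out, scr, cst, tst),
                 one$cost_unrounded, tolerance = 1e-9)
  }
})

test_that("two-stage cost matches direct evaluation at the worked-example cuts", {
  out <- ex_outcome(); scr <- ex_screening(); cst <- ex_costs(); tst <- ex_test()
  # frozen: required_n(5.8) * (1400 + 400/0.5677054 + 200/0.2838527)
  expect_equal(total_cost_twostage(5.8, 5, out, scr, cst, tst),
               107066.3, tolerance = 1e-5)
  # near-perfect surrogate with matched cuts: screening collapses toward n
  scr99 <- ex_screening(rho = 0.999)
  expect_gt(cond_upper(scr99, 5.8, 5.8), 0.95)
  expect_error(total_cost_twostage(5, 5 + 2 * 4.5, out, scr, cst, tst),
               class = "enrichcost_infeasible")
})

test_that("inner prescreen optimization behaves across surrogate quality", {
  out <- ex_outcome(); tst <- ex_test(); cst <- ex_costs()
  r <- optimize_b_given_a(5.8, out, ex_screening(), cst, tst)
  expect_equal(r$b_opt, 5.0)
  # uninformative surrogate: prescreening is pure cost, pushed to the floor
  scr0 <- ex_screening(rho = 0)
  r0 <- optimize_b_given_a(5.3, out, scr0, cst, tst)
  expect_equal(r0$b_opt, 5 - 3 * 2)
})

test_that("nested grid search reproduces the worked-example two-stage optimum", {
  out <- ex_outcome(); scr <- ex_screening(); cst <- ex_costs(); tst <- ex_test()
  d <- optimize_twostage(out, scr, cst, tst)
  expect_equal(d$a_opt, 5.8)
  expect_equal(d$b_opt, 5.0)
  expect_equal(d$cost_rounded, 107600)
  expect_equal(d$cost_unrounded, 107066.3, tolerance = 1e-5)
  expect_equal(d$n_total, 77L)
  expect_equal(d$N_total, 134L)
  expect_equal(d$M_total, 269L)
  expect_equal(d$saving_abs, 10500)
  expect_equal(d$saving_pct, 8.89, tolerance = 1e-2)
  # chain identities
  pz <- upper_tail(5, 2, d$b_opt)
  pj <- enrichcost:::joint_upper(scr, d$a_opt, d$b_opt)
  expect_equal(d$M_star * pz, d$N_star, tolerance = 1e-9)
  expect_equal(d$M_star * pj, d$n_star, tolerance = 1e-9)
  expect_equal(d$N_star * cond_upper(scr, d$a_opt, d$b_opt), d$n_star,
               tolerance = 1e-9)
})

test_that("two-stage optimum dominates one-stage at equal recruitment budget", {
  out <- ex_outcome(); tst <- ex_test(); cst <- ex_costs()
  # deep b_lo so the no-prescreen reduction is effectively in the feasible set
  for (rho in c(0.3, 0.7, 0.9)) {
    scr <- ex_screening(rho = rho)
    grid <- grid_spec(a_lo = -1, a_hi = 11, a_step = 0.25,
                      b_lo = -13, b_hi = 11, b_step = 0.25)
    two <- optimize_twostage(out, scr, cst, tst, grid)
    one <- optimize_onestage(out, scr,
                             cost_structure(c_trt = 700, c_rec = 300),
                             tst, grid)
    expect_lte(two$cost_unrounded, one$cost_unrounded + 1e-6)
  }
})

test_that("enrollment curve is shared and screening curves bracket the one-stage curve", {
  out <- ex_outcome(); scr <- ex_screening(); cst <- ex_costs(); tst <- ex_test()
  grid <- grid_spec(a_lo = 3, a_hi = 8, a_step = 0.25,
                    b_lo = -1, b_hi = 11, b_step = 0.25)
  two <- optimize_twostage(out, scr, cst, tst, grid, keep_grid = TRUE)
  one <- optimize_onestage(out, scr,
                           cost_structure(c_trt = 700, c_rec = 300),
                           tst, grid, keep_grid = TRUE)
  m <- merge(two$grid, one$grid, by = "a", suffixes = c("_two", "_one"))
  # the power constraint fixes n(a) identically under both procedures
  expect_equal(m$n_star_two, m$n_star_one, tolerance = 1e-12)
  # per-group screening sizes: N_two <= N_one <= M_two pointwise
  expect_true(all(m$N_star_two <= m$N_star_one + 1e-9))
  expect_true(all(m$N_star_one <= m$M_star_two + 1e-9))
})

test_that("savings grow with cheaper prescreens and better surrogates", {
  out <- ex_outcome(); scr <- ex_screening(); tst <- ex_test()
  grid <- grid_spec(a_lo = 2, a_hi = 9, a_step = 0.2,
                    b_lo = 2, b_hi = 9, b_step = 0.2)
  sw <- sweep_prescreen_share(c(0.2, 0.5, 0.8), out, scr, tst, grid = grid)
  expect_true(all(diff(sw$cost_unrounded) >= 0))
  sr <- sweep_rho(c(0.3, 0.6, 0.9), out, scr, ex_costs(), tst, grid)
  expect_true(all(diff(sr$cost_unrounded) <= 0))
  # uninformative surrogate at matched budget: essentially no saving
  d0 <- optimize_twostage(out, ex_screening(rho = 0), ex_costs(), tst)
  expect_lt(abs(d0$saving_pct), 0.5)
  expect_equal(d0$b_opt, 5 - 3 * 2)
})
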