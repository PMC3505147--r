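# Worked-example fixtures used across the suite: hot-flash severity
# X ~ N(5, 2^2), surrogate Z with the same marginal, interaction model
# beta = (0, -0.2, 1, -0.25), sigma = 2.5, alpha = 0.05, power 90%.

ex_outcome <- function() outcome_model(beta1 = -0.2, beta3 = -0.25, sigma = 2.5)
ex_screening <- function(rho = 0.7) screening_model(mu_x = 5, sd_x = 2, rho = rho)
ex_costs <- function() cost_structure(c_trt = 700, c_placebo = 700,
                                      c_rec = 300, c_scr = 200, c_pre = 100)
ex_test <- function() test_spec(alpha = 0.05, target_power = 0.90)

# Rejection-sampling Monte-Carlo oracle for truncated-normal moments,
# independent of the Mills-ratio implementation path.
mc_truncated <- function(mu, sd, a, n = 1e6, seed = 1) {
  set.seed(seed)
  x <- rnorm(n, mu, sd)
  x[x >= a]
}
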