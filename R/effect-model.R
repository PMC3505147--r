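# Marginal-effect and power machinery for enrichment designs.
#
# Enrolling only subjects with X >= a turns the interaction model
#   Y = b0 + b1*Trt + b2*X + b3*Trt*X + eps
# into the marginal model Y = l0 + l1*Trt + e among enrollees, with
#   l1(a) = b1 + b3 * E[X | X >= a],
# so stricter eligibility buys a larger detectable arm difference whenever
# b1 and b3 share sign.

#' Marginal treatment effect among enrollees
#'
#' The coefficient `lambda1(a) = beta1 + beta3 * E[X | X >= a]` detected by
#' the two-sample test when enrollment requires baseline severity `X >= a`.
#'
#' @param outcome An [outcome_model()].
#' @param screening A [screening_model()].
#' @param a Severity threshold; may be `-Inf` (no enrichment).
#' @return The marginal effect `lambda1` (a scalar).
#' @export
marginal_effect <- function(outcome, screening, a) {
  stopifnot(inherits(outcome, "outcome_model"),
            inherits(screening, "screening_model"))
  outcome$beta1 +
    outcome$beta3 * trunc_mean(screening$mu_x, screening$sd_x, a)
}

#' Solicit interaction coefficients from two targeted effects
#'
#' Investigators rarely state `beta1` and `beta3` directly; they state the
#' treatment effect they expect at two candidate eligibility cuts. Given
#' targeted marginal effects `lam1` at threshold `a1` and `lam2` at `a2`,
#' solve the 2x2 linear system
#' `lam_j = beta1 + beta3 * E[X | X >= a_j]` for `(beta1, beta3)`.
#'
#' @param a1,a2 Two distinct severity thresholds.
#' @param lam1,lam2 Targeted marginal effects at `a1` and `a2`.
#' @param screening A [screening_model()].
#' @return Named numeric vector `c(beta1 = , beta3 = )`.
#' @export
solve_betas <- function(a1, lam1, a2, lam2, screening) {
  stopifnot(inherits(screening, "screening_model"))
  e1 <- trunc_mean(screening$mu_x, screening$sd_x, a1)
  e2 <- trunc_mean(screening$mu_x, screening$sd_x, a2)
  if (isTRUE(all.equal(e1, e2, tolerance = 1e-12)))
    stop_enrichcost(
      "thresholds give identical truncated means: system is singular",
      "enrichcost_singular_solicitation")
  sol <- solve(matrix(c(1, 1, e1, e2), nrow = 2), c(lam1, lam2))
  c(beta1 = sol[1], beta3 = sol[2])
}

# Variance of the outcome within each arm among enrollees:
#   Var(Y | Trt = 0, X >= a) = sigma^2 + beta2^2           * Var(X | X >= a)
#   Var(Y | Trt = 1, X >= a) = sigma^2 + (beta2 + beta3)^2 * Var(X | X >= a)
arm_variances <- function(outcome, screening, a) {
  vx <- trunc_var(screening$mu_x, screening$sd_x, a)
  c(control = outcome$sigma^2 + outcome$beta2^2 * vx,
    treated = outcome$sigma^2 + (outcome$beta2 + outcome$beta3)^2 * vx)
}

#' Approximate power of the marginal test under enrichment
#'
#' Normal approximation to the power of the two-sided two-sample test of the
#' marginal treatment effect when both arms enroll `n_per_group` subjects with
#' `X >= a`:
#' \deqn{\Phi\!\left(\frac{\sqrt{n}\,|\lambda_1(a)|}
#'   {\sqrt{2\sigma^2 + \{\beta_2^2 + (\beta_2+\beta_3)^2\}\,
#'    \mathrm{Var}(X \mid X \ge a)}} - z_{crit}\right)}
#' The detection tail uses `|lambda1|`; the negligible opposite-tail term is
#' omitted. `n_per_group` may be non-integer (the inversion in
#' [required_n()] relies on that).
#'
#' @param n_per_group Per-arm sample size (real-valued allowed).
#' @param a Severity threshold.
#' @param outcome An [outcome_model()].
#' @param screening A [screening_model()].
#' @param test A [test_spec()].
#' @return Power in (0, 1). When `lambda1(a) = 0` the value is the one-tail
#'   size `pnorm(-z_crit)` and a warning of class
#'   `enrichcost_no_effect` is signalled.
#' @export
power_marginal <- function(n_per_group, a, outcome, screening, test) {
  check_number(n_per_group, "n_per_group", positive = TRUE)
  stopifnot(inherits(test, "test_spec"))
  lam <- marginal_effect(outcome, screening, a)
  if (lam == 0)
    warning(warningCondition(
      "lambda1 = 0 at this threshold: returning the null size level",
      class = "enrichcost_no_effect"))
  denom <- sum(arm_variances(outcome, screening, a))
  stats::pnorm(sqrt(n_per_group) * abs(lam) / sqrt(denom) - z_crit(test))
}

#' Per-group sample size achieving the target power
#'
#' Closed-form inversion of the power approximation:
#' `n* = ((z_power + z_crit) / |lambda1|)^2 * (Var1 + Var2)`. Returns the
#' unrounded real value; integer rounding conventions live in the design
#' modules so they are applied in exactly one place.
#'
#' @inheritParams power_marginal
#' @return Unrounded per-group sample size `n*` with
#'   `power_marginal(n*, a, ...) == target_power`.
#' @export
required_n <- function(a, outcome, screening, test) {
  stopifnot(inherits(test, "test_spec"))
  lam <- marginal_effect(outcome, screening, a)
  if (lam == 0)
    stop_enrichcost("lambda1 = 0: target power is unattainable at this threshold",
                    "enrichcost_unattainable_power")
  denom <- sum(arm_variances(outcome, screening, a))
  ((stats::qnorm(test$target_power) + z_crit(test))^2 * denom) / lam^2
}

#' Power with unequal group sizes
#'
#' Generalizes [power_marginal()] to `n1` control and `n2` treated enrollees,
#' with noncentrality `|lambda1| / sqrt(Var1/n1 + Var2/n2)`. Reduces exactly
#' to the equal-allocation formula at `n1 = n2`.
#'
#' @param n1,n2 Control- and treated-arm sizes (real-valued allowed).
#' @inheritParams power_marginal
#' @return Power in (0, 1).
#' @export
power_unequal <- function(n1, n2, a, outcome, screening, test) {
  check_number(n1, "n1", positive = TRUE)
  check_number(n2, "n2", positive = TRUE)
  stopifnot(inherits(test, "test_spec"))
  lam <- marginal_effect(outcome, screening, a)
  if (lam == 0)
    warning(warningCondition(
      "lambda1 = 0 at this threshold: returning the null size level",
      class = "enrichcost_no_effect"))
  v <- arm_variances(outcome, screening, a)
  stats::pnorm(abs(lam) / sqrt(v[["control"]] / n1 + v[["treated"]] / n2) -
                 z_crit(test))
}
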