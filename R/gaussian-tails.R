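# Numerically exact truncated-normal moments and bivariate-normal
# upper-rectangle probabilities. Everything downstream (effect sizes, power,
# screening sizes, joint pass rates) is built on these five functions.

# Conditioning tails below this are treated as degenerate: Mills-ratio
# arithmetic loses precision well before the probability underflows.
.TAIL_EPS <- 1e-12

# Standard-normal hazard phi(x) / (1 - Phi(x)), computed on the log scale so
# it stays accurate deep in the upper tail.
hazard <- function(x) {
  exp(stats::dnorm(x, log = TRUE) -
        stats::pnorm(x, lower.tail = FALSE, log.p = TRUE))
}

#' Normal upper-tail probability
#'
#' `P(X >= a)` for `X ~ N(mu, sd^2)`. `a = -Inf` is an exact "no truncation"
#' path returning 1.
#'
#' @param mu,sd Mean and standard deviation (`sd > 0`).
#' @param a Lower threshold; may be `-Inf`.
#' @return Probability in `[0, 1]`.
#' @export
upper_tail <- function(mu, sd, a) {
  check_number(mu, "mu"); check_number(sd, "sd", positive = TRUE)
  if (identical(a, -Inf)) return(1)
  check_number(a, "a")
  stats::pnorm(a, mean = mu, sd = sd, lower.tail = FALSE)
}

#' Truncated-normal mean
#'
#' `E[X | X >= a]` for `X ~ N(mu, sd^2)`, via the Mills-ratio hazard:
#' `mu + sd * h((a - mu)/sd)` with `h(x) = dnorm(x) / (1 - pnorm(x))`.
#'
#' @inheritParams upper_tail
#' @return The conditional mean; always `>= max(mu, a)`.
#' @export
trunc_mean <- function(mu, sd, a) {
  check_number(mu, "mu"); check_number(sd, "sd", positive = TRUE)
  if (identical(a, -Inf)) return(mu)
  check_number(a, "a")
  alpha <- (a - mu) / sd
  if (stats::pnorm(alpha, lower.tail = FALSE) < .TAIL_EPS)
    stop_enrichcost(
      sprintf("truncation at a = %g leaves tail probability < %g", a, .TAIL_EPS),
      "enrichcost_degenerate_truncation")
  mu + sd * hazard(alpha)
}

#' Truncated-normal variance
#'
#' `Var(X | X >= a)` for `X ~ N(mu, sd^2)`:
#' `sd^2 * (1 + alpha*h(alpha) - h(alpha)^2)`, `alpha = (a - mu)/sd`.
#'
#' @inheritParams upper_tail
#' @return A value in `(0, sd^2]`, nonincreasing in `a`.
#' @export
trunc_var <- function(mu, sd, a) {
  check_number(mu, "mu"); check_number(sd, "sd", positive = TRUE)
  if (identical(a, -Inf)) return(sd^2)
  check_number(a, "a")
  alpha <- (a - mu) / sd
  if (stats::pnorm(alpha, lower.tail = FALSE) < .TAIL_EPS)
    stop_enrichcost(
      sprintf("truncation at a = %g leaves tail probability < %g", a, .TAIL_EPS),
      "enrichcost_degenerate_truncation")
  h <- hazard(alpha)
  sd^2 * (1 + alpha * h - h^2)
}

#' Bivariate-normal upper-rectangle probability
#'
#' `P(U >= u, V >= v)` for standard normals `(U, V)` with correlation `rho`,
#' by one-dimensional adaptive quadrature of the conditional-normal form
#' `integral over t >= v of dnorm(t) * pnorm((rho*t - u)/sqrt(1 - rho^2))`.
#' Deterministic and smooth in its arguments (absolute accuracy ~1e-10), which
#' the threshold optimizers rely on.
#'
#' @param u,v Standardized lower limits; either may be `-Inf`.
#' @param rho Correlation, strictly inside (-1, 1).
#' @return Probability in `[0, 1]`, symmetric in `(u, v)`.
#' @export
bvn_upper_rect <- function(u, v, rho) {
  check_number(rho, "rho")
  if (abs(rho) >= 1)
    stop_enrichcost("`rho` must satisfy -1 < rho < 1",
                    "enrichcost_invalid_parameter")
  u_inf <- identical(u, -Inf); v_inf <- identical(v, -Inf)
  if (!u_inf) check_number(u, "u")
  if (!v_inf) check_number(v, "v")
  if (u_inf && v_inf) return(1)
  if (u_inf) return(stats::pnorm(v, lower.tail = FALSE))
  if (v_inf) return(stats::pnorm(u, lower.tail = FALSE))
  if (rho == 0)
    return(stats::pnorm(u, lower.tail = FALSE) *
             stats::pnorm(v, lower.tail = FALSE))
  s <- sqrt(1 - rho^2)
  val <- stats::integrate(function(t) stats::dnorm(t) *
                            stats::pnorm((rho * t - u) / s),
                          lower = v, upper = Inf,
                          rel.tol = 1e-12, abs.tol = 1e-13,
                          subdivisions = 500L)$value
  min(max(val, 0), 1)
}

#' Conditional screening pass probability
#'
#' `P(X >= a | Z >= b)` under a [screening_model()]: the fraction of
#' prescreen survivors (`Z >= b`) who also pass the on-site severity screen
#' (`X >= a`). Computed as the standardized joint upper rectangle divided by
#' the `Z` tail.
#'
#' @param model A [screening_model()].
#' @param a Severity threshold (on `X`); may be `-Inf`.
#' @param b Prescreen threshold (on `Z`); may be `-Inf`.
#' @return Probability in `[0, 1]`.
#' @export
cond_upper <- function(model, a, b) {
  stopifnot(inherits(model, "screening_model"))
  pz <- upper_tail(model$mu_z, model$sd_z, b)
  if (pz < .TAIL_EPS)
    stop_enrichcost(
      sprintf("prescreen tail P(Z >= %g) < %g: degenerate conditioning", b, .TAIL_EPS),
      "enrichcost_degenerate_truncation")
  u <- if (identical(a, -Inf)) -Inf else (a - model$mu_x) / model$sd_x
  v <- if (identical(b, -Inf)) -Inf else (b - model$mu_z) / model$sd_z
  bvn_upper_rect(u, v, model$rho) / pz
}

# Joint pass probability P(X >= a, Z >= b) on the original scale.
joint_upper <- function(model, a, b) {
  u <- if (identical(a, -Inf)) -Inf else (a - model$mu_x) / model$sd_x
  v <- if (identical(b, -Inf)) -Inf else (b - model$mu_z) / model$sd_z
  bvn_upper_rect(u, v, model$rho)
}
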