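#' @keywords internal
stop_enrichcost <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "enrichcost_error"),
                      call = call))
}

check_number <- function(x, name, positive = FALSE, nonnegative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_enrichcost(sprintf("`%s` must be a single finite number", name),
                    "enrichcost_invalid_parameter")
  if (positive && x <= 0)
    stop_enrichcost(sprintf("`%s` must be > 0", name),
                    "enrichcost_invalid_parameter")
  if (nonnegative && x < 0)
    stop_enrichcost(sprintf("`%s` must be >= 0", name),
                    "enrichcost_invalid_parameter")
  x
}

#' Screening-variable model
#'
#' Joint distribution of the baseline severity `X` (the screening variable,
#' on which enrollment requires `X >= a`) and an inexpensive surrogate `Z`
#' (the prescreening variable, cut at `Z >= b` in two-stage designs).
#' `(X, Z)` are bivariate normal with correlation `rho`.
#'
#' @param mu_x,sd_x Mean and standard deviation of severity `X` (severity-scale
#'   units); `sd_x > 0`.
#' @param mu_z,sd_z Mean and standard deviation of the surrogate `Z`; defaults
#'   mirror the `X` marginal.
#' @param rho Correlation between `X` and `Z`, strictly inside (-1, 1).
#' @return An object of class `screening_model`.
#' @examples
#' sm <- screening_model(mu_x = 5, sd_x = 2, rho = 0.7)
#' upper_tail(sm$mu_x, sm$sd_x, 5.3)
#' @export
screening_model <- function(mu_x, sd_x, mu_z = mu_x, sd_z = sd_x, rho = 0) {
  check_number(mu_x, "mu_x"); check_number(sd_x, "sd_x", positive = TRUE)
  check_number(mu_z, "mu_z"); check_number(sd_z, "sd_z", positive = TRUE)
  check_number(rho, "rho")
  if (abs(rho) >= 1)
    stop_enrichcost("`rho` must satisfy -1 < rho < 1",
                    "enrichcost_invalid_parameter")
  structure(list(mu_x = mu_x, sd_x = sd_x, mu_z = mu_z, sd_z = sd_z,
                 rho = rho),
            class = "screening_model")
}

#' Outcome regression model
#'
#' Linear model for post-treatment severity
#' `Y = beta0 + beta1*Trt + beta2*X + beta3*Trt*X + eps`,
#' `eps ~ N(0, sigma^2)`, where `Trt` is the 0/1 randomized-arm indicator and
#' `X` the baseline severity. A nonzero `beta3` encodes a
#' treatment-by-baseline-severity interaction: the arm difference among
#' enrollees with `X >= a` grows with the threshold `a` when `beta1` and
#' `beta3` share sign.
#'
#' @param beta0 Intercept (control-arm mean at `X = 0`).
#' @param beta1 Main treatment effect.
#' @param beta2 Baseline-severity slope.
#' @param beta3 Treatment-by-severity interaction.
#' @param sigma Error standard deviation; `sigma > 0`.
#' @return An object of class `outcome_model`.
#' @export
outcome_model <- function(beta0 = 0, beta1, beta2 = 1, beta3, sigma) {
  check_number(beta0, "beta0"); check_number(beta1, "beta1")
  check_number(beta2, "beta2"); check_number(beta3, "beta3")
  check_number(sigma, "sigma", positive = TRUE)
  structure(list(beta0 = beta0, beta1 = beta1, beta2 = beta2, beta3 = beta3,
                 sigma = sigma),
            class = "outcome_model")
}

#' Hypothesis-test specification
#'
#' Two-sided significance level and target power for the marginal two-sample
#' test of the treatment effect among enrollees. By default the critical value
#' is the conventional 1.96 when `alpha = 0.05` (`use_z_critical = TRUE`);
#' set the flag to `FALSE` for the exact `qnorm(1 - alpha/2)`.
#'
#' @param alpha Two-sided significance level, in (0, 1).
#' @param target_power Required power, in (0, 1).
#' @param use_z_critical Use the printed 1.96-style rounded critical value
#'   (two decimals) rather than the exact normal quantile.
#' @return An object of class `test_spec`.
#' @export
test_spec <- function(alpha = 0.05, target_power = 0.90,
                      use_z_critical = TRUE) {
  check_number(alpha, "alpha"); check_number(target_power, "target_power")
  if (alpha <= 0 || alpha >= 1)
    stop_enrichcost("`alpha` must be in (0, 1)",
                    "enrichcost_invalid_parameter")
  if (target_power <= 0 || target_power >= 1)
    stop_enrichcost("`target_power` must be in (0, 1)",
                    "enrichcost_invalid_parameter")
  structure(list(alpha = alpha, target_power = target_power,
                 use_z_critical = isTRUE(use_z_critical)),
            class = "test_spec")
}

# Critical value of the two-sided test on the normal scale.
z_crit <- function(test) {
  z <- stats::qnorm(1 - test$alpha / 2)
  if (test$use_z_critical) round(z, 2) else z
}

#' Per-subject cost structure
#'
#' Unit costs of an enrichment trial. One-stage designs charge `c_rec` per
#' screened candidate; two-stage designs split recruitment into a cheap
#' prescreen (`c_pre` per candidate contacted) and an on-site screen
#' (`c_scr` per candidate passing the prescreen). Enrolled subjects cost
#' `c_trt` (treatment arm) or `c_placebo` (control arm). Currency is unitless
#' in all computations; `currency` is a label carried into reports.
#'
#' @param c_trt,c_placebo Per-enrollee intervention and control costs.
#' @param c_rec One-stage per-screen recruitment cost.
#' @param c_scr,c_pre Two-stage on-site screening and prescreening costs.
#' @param currency Label, default `"USD"`.
#' @return An object of class `cost_structure`.
#' @export
cost_structure <- function(c_trt, c_placebo = c_trt, c_rec = NA_real_,
                           c_scr = NA_real_, c_pre = NA_real_,
                           currency = "USD") {
  for (nm in c("c_trt", "c_placebo")) check_number(get(nm), nm, nonnegative = TRUE)
  for (nm in c("c_rec", "c_scr", "c_pre")) {
    v <- get(nm)
    if (!is.na(v)) check_number(v, nm, nonnegative = TRUE)
  }
  structure(list(c_trt = c_trt, c_placebo = c_placebo, c_rec = c_rec,
                 c_scr = c_scr, c_pre = c_pre, currency = currency),
            class = "cost_structure")
}

#' Threshold search grids
#'
#' Equally spaced grids over the severity cut `a` (on `X`) and, for two-stage
#' designs, the prescreen cut `b` (on `Z`). The defaults, derived from a
#' [screening_model()], span mean +/- 3 SD in steps of 0.1 — the resolution at
#' which optima are conventionally reported.
#'
#' @param a_lo,a_hi,a_step Grid over the screening threshold `a`.
#' @param b_lo,b_hi,b_step Grid over the prescreening threshold `b`.
#' @param refine Reserved flag for local refinement past the grid resolution
#'   (off by default; reported optima then sit exactly on the grid).
#' @return An object of class `grid_spec`.
#' @seealso [default_grid()]
#' @export
grid_spec <- function(a_lo, a_hi, a_step = 0.1,
                      b_lo = a_lo, b_hi = a_hi, b_step = a_step,
                      refine = FALSE) {
  for (nm in c("a_lo", "a_hi", "b_lo", "b_hi")) check_number(get(nm), nm)
  check_number(a_step, "a_step", positive = TRUE)
  check_number(b_step, "b_step", positive = TRUE)
  if (a_lo >= a_hi || b_lo >= b_hi)
    stop_enrichcost("grid bounds must satisfy lo < hi",
                    "enrichcost_invalid_parameter")
  g <- structure(list(a_lo = a_lo, a_hi = a_hi, a_step = a_step,
                      b_lo = b_lo, b_hi = b_hi, b_step = b_step,
                      refine = isTRUE(refine)),
                 class = "grid_spec")
  if (length(grid_points(g, "a")) < 2L || length(grid_points(g, "b")) < 2L)
    stop_enrichcost("each grid must contain at least 2 points",
                    "enrichcost_invalid_parameter")
  g
}

#' @rdname grid_spec
#' @param screening A [screening_model()] supplying the default spans.
#' @export
default_grid <- function(screening, a_step = 0.1, b_step = a_step) {
  grid_spec(a_lo = screening$mu_x - 3 * screening$sd_x,
            a_hi = screening$mu_x + 3 * screening$sd_x, a_step = a_step,
            b_lo = screening$mu_z - 3 * screening$sd_z,
            b_hi = screening$mu_z + 3 * screening$sd_z, b_step = b_step)
}

grid_points <- function(grid, which = c("a", "b")) {
  which <- match.arg(which)
  lo <- grid[[paste0(which, "_lo")]]
  hi <- grid[[paste0(which, "_hi")]]
  st <- grid[[paste0(which, "_step")]]
  seq(lo, hi, by = st)
}

#' @export
print.screening_model <- function(x, ...) {
  cat(sprintf("Screening model: X ~ N(%g, %g^2), Z ~ N(%g, %g^2), rho = %g\n",
              x$mu_x, x$sd_x, x$mu_z, x$sd_z, x$rho))
  invisible(x)
}

#' @export
print.outcome_model <- function(x, ...) {
  cat(sprintf(
    "Outcome model: Y = %g + %g*Trt + %g*X + %g*Trt*X + eps, eps ~ N(0, %g^2)\n",
    x$beta0, x$beta1, x$beta2, x$beta3, x$sigma))
  invisible(x)
}
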