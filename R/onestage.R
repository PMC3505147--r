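# One-stage screening designs: every candidate is screened on X at cost
# c_rec; those with X >= a enroll. Minimize
#   (c_trt + c_placebo) * n + 2 * c_rec * N   with  N = n / P(X >= a)
# over the severity threshold a, subject to power(n, a) >= target.

# Grid points with vanishing eligibility are skipped: N = n / P(X >= a)
# diverges as the tail closes.
.FEAS_EPS <- 1e-4

# Integer rounding conventions, applied in exactly one place:
# enrolled total is rounded UP (conservative for power); screened and
# prescreened totals to the nearest integer, halves away from zero.
round_half_up <- function(x) floor(x + 0.5)

round_sizes_onestage <- function(n_star, N_star) {
  list(n_total = as.integer(ceiling(2 * n_star)),
       N_total = as.integer(round_half_up(2 * N_star)))
}

#' Evaluate a one-stage design at a fixed severity threshold
#'
#' Solves the power constraint for the unrounded per-group enrollment
#' `n* = required_n(a)`, derives the per-group screening size
#' `N* = n* / P(X >= a)`, and prices the design both on the continuous scale
#' (`cost_unrounded`, the optimization objective) and from the integer totals
#' a real trial would use (`cost_rounded`).
#'
#' @param a Severity threshold for enrollment (`X >= a`).
#' @param outcome An [outcome_model()].
#' @param screening A [screening_model()].
#' @param costs A [cost_structure()] with `c_rec` set.
#' @param test A [test_spec()].
#' @return An object of class `onestage_design`: threshold, unrounded
#'   per-group sizes `n_star`/`N_star`, integer totals `n_total`/`N_total`,
#'   both costs, the marginal effect `lambda1`, and the achieved power at the
#'   rounded size.
#' @examples
#' out <- outcome_model(beta1 = -0.2, beta3 = -0.25, sigma = 2.5)
#' scr <- screening_model(mu_x = 5, sd_x = 2)
#' cst <- cost_structure(c_trt = 700, c_rec = 300)
#' evaluate_onestage(5.3, out, scr, cst, test_spec())
#' @export
evaluate_onestage <- function(a, outcome, screening, costs, test) {
  stopifnot(inherits(costs, "cost_structure"))
  if (is.na(costs$c_rec))
    stop_enrichcost("one-stage designs require `c_rec`",
                    "enrichcost_invalid_parameter")
  p_a <- upper_tail(screening$mu_x, screening$sd_x, a)
  n_star <- required_n(a, outcome, screening, test)
  N_star <- n_star / p_a
  sizes <- round_sizes_onestage(n_star, N_star)
  cost_unrounded <- (costs$c_trt + costs$c_placebo) * n_star +
    2 * costs$c_rec * N_star
  cost_rounded <- (costs$c_trt + costs$c_placebo) / 2 * sizes$n_total +
    costs$c_rec * sizes$N_total
  structure(list(
    a_opt = a,
    n_star = n_star, N_star = N_star,
    n_total = sizes$n_total, N_total = sizes$N_total,
    cost_unrounded = cost_unrounded, cost_rounded = cost_rounded,
    lambda1 = marginal_effect(outcome, screening, a),
    power_achieved = power_marginal(sizes$n_total / 2, a, outcome,
                                    screening, test),
    inputs = list(outcome = outcome, screening = screening, costs = costs,
                  test = test)),
    class = "onestage_design")
}

#' Cost-optimal one-stage design by threshold grid search
#'
#' Evaluates the continuous cost objective on the `a`-grid and returns the
#' minimizing design. Ties are broken toward the smaller threshold (the less
#' restrictive eligibility criterion). Grid points where eligibility
#' essentially vanishes (`P(X >= a) < 1e-4`) are skipped as infeasible.
#'
#' @inheritParams evaluate_onestage
#' @param grid A [grid_spec()]; defaults to [default_grid()] of the screening
#'   model (mean +/- 3 SD, step 0.1).
#' @param keep_grid Keep the full evaluated threshold sweep (one row per
#'   feasible grid point) as element `$grid` — the data behind the classic
#'   cost and sample-size curves.
#' @return An `onestage_design` (see [evaluate_onestage()]); with
#'   `keep_grid = TRUE`, also `$grid`, a data.frame with columns
#'   `a`, `n_star`, `N_star`, `n_total`, `N_total`, `cost_unrounded`.
#' @export
optimize_onestage <- function(outcome, screening, costs, test = test_spec(),
                              grid = default_grid(screening),
                              keep_grid = FALSE) {
  stopifnot(inherits(grid, "grid_spec"))
  as_ <- grid_points(grid, "a")
  rows <- vector("list", length(as_))
  best <- NULL
  for (i in seq_along(as_)) {
    a <- as_[i]
    if (upper_tail(screening$mu_x, screening$sd_x, a) < .FEAS_EPS) next
    d <- evaluate_onestage(a, outcome, screening, costs, test)
    rows[[i]] <- data.frame(a = a, n_star = d$n_star, N_star = d$N_star,
                            n_total = d$n_total, N_total = d$N_total,
                            cost_unrounded = d$cost_unrounded)
    if (is.null(best) || d$cost_unrounded < best$cost_unrounded) best <- d
  }
  if (is.null(best))
    stop_enrichcost("no feasible grid point for the one-stage design",
                    "enrichcost_infeasible")
  if (keep_grid) best$grid <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  best
}

#' Sweep the screening share of a fixed per-subject budget
#'
#' Holds the sum of the per-screen recruitment cost and the per-arm
#' intervention cost fixed (`c_rec + c_trt = budget`, with
#' `c_placebo = c_trt`) and re-optimizes the one-stage design as recruitment
#' takes a growing share. Optimum total cost rises and the optimum screening
#' size falls as screening gets relatively more expensive.
#'
#' @param shares Vector of recruitment shares `c_rec / budget` in (0, 1).
#' @param budget Fixed sum `c_rec + c_trt`, default 1000.
#' @inheritParams optimize_onestage
#' @return A data.frame with one row per share: `share`, `c_rec`, `c_trt`,
#'   `a_opt`, `cost_unrounded`, `cost_rounded`, `N_total`, `n_total`.
#' @export
sweep_screening_share <- function(shares, outcome, screening,
                                  test = test_spec(), budget = 1000,
                                  grid = default_grid(screening)) {
  stopifnot(all(shares > 0 & shares < 1))
  rows <- lapply(shares, function(s) {
    cst <- cost_structure(c_trt = budget * (1 - s), c_rec = budget * s)
    d <- optimize_onestage(outcome, screening, cst, test, grid)
    data.frame(share = s, c_rec = cst$c_rec, c_trt = cst$c_trt,
               a_opt = d$a_opt, cost_unrounded = d$cost_unrounded,
               cost_rounded = d$cost_rounded,
               N_total = d$N_total, n_total = d$n_total)
  })
  do.call(rbind, rows)
}

#' @export
print.onestage_design <- function(x, ...) {
  cur <- x$inputs$costs$currency
  cat("One-stage enrichment design\n")
  cat(sprintf("  severity threshold a = %g (lambda1 = %.4f)\n",
              x$a_opt, x$lambda1))
  cat(sprintf("  per-group sizes: enroll %.2f, screen %.2f (unrounded)\n",
              x$n_star, x$N_star))
  cat(sprintf("  integer totals:  enroll %d, screen %d\n",
              x$n_total, x$N_total))
  cat(sprintf("  cost: %s %.0f (objective %.1f); achieved power %.3f\n",
              cur, x$cost_rounded, x$cost_unrounded, x$power_achieved))
  invisible(x)
}
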