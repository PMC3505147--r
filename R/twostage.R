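# Two-stage screening designs: candidates are first prescreened on the cheap
# surrogate Z (cost c_pre each); survivors of Z >= b are screened on X
# (cost c_scr each); those with X >= a enroll. With per-group prescreen size
# M, screen size N and enrollment n,
#   N = M * P(Z >= b),   n = N * P(X >= a | Z >= b) = M * P(X >= a, Z >= b),
# so the total cost for a given n = required_n(a) collapses to
#   n * ( c_trt + c_placebo + 2*c_scr / P(X >= a | Z >= b)
#                           + 2*c_pre / P(X >= a, Z >= b) ).
# The power constraint involves a only, so b can be optimized inside a.

check_twostage_costs <- function(costs) {
  stopifnot(inherits(costs, "cost_structure"))
  if (is.na(costs$c_scr) || is.na(costs$c_pre))
    stop_enrichcost("two-stage designs require `c_scr` and `c_pre`",
                    "enrichcost_invalid_parameter")
}

#' Total cost of a two-stage design at fixed thresholds
#'
#' Evaluates the two-stage cost objective at screening cut `a` (on `X`) and
#' prescreening cut `b` (on `Z`), with the per-group enrollment fixed at
#' `required_n(a)`. Power does not involve `b`: enrollees all pass `X >= a`,
#' and the design conservatively prices — rather than re-powers — the extra
#' `Z >= b` conditioning.
#'
#' @param a Screening threshold on `X`.
#' @param b Prescreening threshold on `Z`; may be `-Inf` (prescreen filters
#'   nobody, reducing to one-stage with `c_rec = c_pre + c_scr`).
#' @param outcome An [outcome_model()].
#' @param screening A [screening_model()].
#' @param costs A [cost_structure()] with `c_scr` and `c_pre` set.
#' @param test A [test_spec()].
#' @return Total unrounded cost (scalar).
#' @export
total_cost_twostage <- function(a, b, outcome, screening, costs, test) {
  check_twostage_costs(costs)
  p_joint <- joint_upper(screening, a, b)
  if (p_joint < .FEAS_EPS)
    stop_enrichcost(
      sprintf("joint tail P(X >= %g, Z >= %g) < %g: infeasible point",
              a, b, .FEAS_EPS),
      "enrichcost_infeasible")
  p_cond <- p_joint / upper_tail(screening$mu_z, screening$sd_z, b)
  n_star <- required_n(a, outcome, screening, test)
  n_star * (costs$c_trt + costs$c_placebo +
              2 * costs$c_scr / p_cond + 2 * costs$c_pre / p_joint)
}

#' Optimal prescreen cut for a fixed screening cut
#'
#' Scans the `b`-grid for the prescreening threshold minimizing the two-stage
#' cost at fixed `a`. Ties go to the smaller `b`. Grid points with joint pass
#' probability below 1e-4 are infeasible and skipped (this also caps the
#' degenerate free-prescreening limit `c_pre = 0`, where the objective keeps
#' falling as `b` rises).
#'
#' @inheritParams total_cost_twostage
#' @param grid A [grid_spec()] supplying the `b`-grid.
#' @return A list with `b_opt` and `cost` (unrounded).
#' @export
optimize_b_given_a <- function(a, outcome, screening, costs,
                               test = test_spec(),
                               grid = default_grid(screening)) {
  bs <- grid_points(grid, "b")
  b_opt <- NA_real_; best <- Inf
  for (b in bs) {
    if (joint_upper(screening, a, b) < .FEAS_EPS) next
    v <- total_cost_twostage(a, b, outcome, screening, costs, test)
    if (v < best) { best <- v; b_opt <- b }
  }
  if (!is.finite(best))
    stop_enrichcost("no feasible prescreen threshold at this screening cut",
                    "enrichcost_infeasible")
  list(b_opt = b_opt, cost = best)
}

#' Cost-optimal two-stage design by nested grid search
#'
#' Outer scan over the screening cut `a`, inner scan over the prescreen cut
#' `b`; returns the design minimizing the continuous cost objective, with
#' integer totals (enrolled rounded up, screened and prescreened to nearest)
#' and the saving relative to the one-stage optimum under the same combined
#' per-subject recruitment cost `c_rec = c_pre + c_scr`.
#'
#' @inheritParams total_cost_twostage
#' @param grid A [grid_spec()] for both threshold grids.
#' @param keep_grid Keep the per-`a` profile (inner-optimized `b` and sizes)
#'   as element `$grid` — the data behind the two-stage versus one-stage
#'   comparison curves.
#' @return An object of class `twostage_design` with thresholds
#'   `a_opt`/`b_opt`, unrounded per-group sizes `n_star`/`N_star`/`M_star`,
#'   integer totals, both costs, and `saving_abs`/`saving_pct` versus the
#'   one-stage rounded optimum.
#' @examples
#' out <- outcome_model(beta1 = -0.2, beta3 = -0.25, sigma = 2.5)
#' scr <- screening_model(mu_x = 5, sd_x = 2, rho = 0.7)
#' cst <- cost_structure(c_trt = 700, c_scr = 200, c_pre = 100)
#' \donttest{optimize_twostage(out, scr, cst)}
#' @export
optimize_twostage <- function(outcome, screening, costs, test = test_spec(),
                              grid = default_grid(screening),
                              keep_grid = FALSE) {
  check_twostage_costs(costs)
  stopifnot(inherits(grid, "grid_spec"))
  as_ <- grid_points(grid, "a")
  rows <- vector("list", length(as_))
  best <- NULL
  for (i in seq_along(as_)) {
    a <- as_[i]
    if (upper_tail(screening$mu_x, screening$sd_x, a) < .FEAS_EPS) next
    inner <- tryCatch(
      optimize_b_given_a(a, outcome, screening, costs, test, grid),
      enrichcost_infeasible = function(e) NULL)
    if (is.null(inner)) next
    if (keep_grid) {
      n_star <- required_n(a, outcome, screening, test)
      pj <- joint_upper(screening, a, inner$b_opt)
      M_star <- n_star / pj
      N_star <- M_star * upper_tail(screening$mu_z, screening$sd_z,
                                    inner$b_opt)
      rows[[i]] <- data.frame(a = a, b_opt = inner$b_opt,
                              n_star = n_star, N_star = N_star,
                              M_star = M_star, cost_unrounded = inner$cost)
    }
    if (is.null(best) || inner$cost < best$cost)
      best <- list(a = a, b = inner$b_opt, cost = inner$cost)
  }
  if (is.null(best))
    stop_enrichcost("no feasible (a, b) point for the two-stage design",
                    "enrichcost_infeasible")

  a <- best$a; b <- best$b
  n_star <- required_n(a, outcome, screening, test)
  p_joint <- joint_upper(screening, a, b)
  p_z <- upper_tail(screening$mu_z, screening$sd_z, b)
  M_star <- n_star / p_joint
  N_star <- M_star * p_z
  n_total <- as.integer(ceiling(2 * n_star))
  N_total <- as.integer(round_half_up(2 * N_star))
  M_total <- as.integer(round_half_up(2 * M_star))
  cost_rounded <- (costs$c_trt + costs$c_placebo) / 2 * n_total +
    costs$c_scr * N_total + costs$c_pre * M_total

  one <- optimize_onestage(
    outcome, screening,
    cost_structure(c_trt = costs$c_trt, c_placebo = costs$c_placebo,
                   c_rec = costs$c_pre + costs$c_scr,
                   currency = costs$currency),
    test, grid)

  structure(list(
    a_opt = a, b_opt = b,
    n_star = n_star, N_star = N_star, M_star = M_star,
    n_total = n_total, N_total = N_total, M_total = M_total,
    cost_unrounded = best$cost, cost_rounded = cost_rounded,
    saving_abs = one$cost_rounded - cost_rounded,
    saving_pct = 100 * (one$cost_rounded - cost_rounded) / one$cost_rounded,
    lambda1 = marginal_effect(outcome, screening, a),
    power_achieved = power_marginal(n_total / 2, a, outcome, screening, test),
    onestage = one,
    grid = if (keep_grid) do.call(rbind, rows[!vapply(rows, is.null, TRUE)]),
    inputs = list(outcome = outcome, screening = screening, costs = costs,
                  test = test)),
    class = "twostage_design")
}

#' Sweep the prescreening share of the recruitment budget
#'
#' Holds `c_pre + c_scr` fixed and re-optimizes the two-stage design as
#' prescreening takes a growing share of the combined recruitment cost. The
#' cheaper the prescreen relative to the screen, the more the two-stage
#' procedure saves, so the optimum cost is nondecreasing in the share.
#'
#' @param shares Vector of prescreen shares `c_pre / (c_pre + c_scr)` in
#'   (0, 1).
#' @param recruit_total Fixed sum `c_pre + c_scr`, default 300.
#' @inheritParams optimize_twostage
#' @return A data.frame with one row per share: `share`, `c_pre`, `c_scr`,
#'   `a_opt`, `b_opt`, `cost_unrounded`, `cost_rounded`, and totals.
#' @export
sweep_prescreen_share <- function(shares, outcome, screening,
                                  test = test_spec(), recruit_total = 300,
                                  c_trt = 700, c_placebo = c_trt,
                                  grid = default_grid(screening)) {
  stopifnot(all(shares > 0 & shares < 1))
  rows <- lapply(shares, function(s) {
    cst <- cost_structure(c_trt = c_trt, c_placebo = c_placebo,
                          c_scr = recruit_total * (1 - s),
                          c_pre = recruit_total * s)
    d <- optimize_twostage(outcome, screening, cst, test, grid)
    data.frame(share = s, c_pre = cst$c_pre, c_scr = cst$c_scr,
               a_opt = d$a_opt, b_opt = d$b_opt,
               cost_unrounded = d$cost_unrounded,
               cost_rounded = d$cost_rounded,
               M_total = d$M_total, N_total = d$N_total, n_total = d$n_total)
  })
  do.call(rbind, rows)
}

#' Sweep the surrogate quality
#'
#' Re-optimizes the two-stage design over a vector of `X`-`Z` correlations at
#' fixed costs. A better surrogate lets the prescreen discard more eventual
#' screen-failures, so the optimum cost is nonincreasing in `rho` (for
#' `rho >= 0`).
#'
#' @param rhos Vector of correlations, each strictly inside (-1, 1).
#' @inheritParams optimize_twostage
#' @return A data.frame with one row per `rho`: `rho`, `a_opt`, `b_opt`,
#'   `cost_unrounded`, `cost_rounded`, and totals.
#' @export
sweep_rho <- function(rhos, outcome, screening, costs, test = test_spec(),
                      grid = default_grid(screening)) {
  check_twostage_costs(costs)
  rows <- lapply(rhos, function(r) {
    scr <- screening_model(mu_x = screening$mu_x, sd_x = screening$sd_x,
                           mu_z = screening$mu_z, sd_z = screening$sd_z,
                           rho = r)
    d <- optimize_twostage(outcome, scr, costs, test, grid)
    data.frame(rho = r, a_opt = d$a_opt, b_opt = d$b_opt,
               cost_unrounded = d$cost_unrounded,
               cost_rounded = d$cost_rounded,
               M_total = d$M_total, N_total = d$N_total, n_total = d$n_total)
  })
  do.call(rbind, rows)
}

#' @export
print.twostage_design <- function(x, ...) {
  cur <- x$inputs$costs$currency
  cat("Two-stage enrichment design (prescreen on Z, screen on X)\n")
  cat(sprintf("  screening cut a = %g (on X), prescreen cut b = %g (on Z)\n",
              x$a_opt, x$b_opt))
  cat(sprintf("  per-group sizes: enroll %.2f, screen %.2f, prescreen %.2f\n",
              x$n_star, x$N_star, x$M_star))
  cat(sprintf("  integer totals:  enroll %d, screen %d, prescreen %d\n",
              x$n_total, x$N_total, x$M_total))
  cat(sprintf("  cost: %s %.0f (objective %.1f); achieved power %.3f\n",
              cur, x$cost_rounded, x$cost_unrounded, x$power_achieved))
  cat(sprintf("  saving vs one-stage optimum: %s %.0f (%.1f%%)\n",
              cur, x$saving_abs, x$saving_pct))
  invisible(x)
}
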