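# Monte-Carlo verification of designed trials: simulate candidates from the
# bivariate screening model, run the recruitment pipeline with the designed
# cut-offs and sizes, generate outcomes from the interaction model, apply the
# two-sample test, and summarize empirical power, type-I error, and realized
# cost over seeded replicates.

.CANDIDATE_CAP <- 1e7  # per-replicate candidate budget before giving up

#' Simulation specification
#'
#' @param replicates Number of simulated trials, `>= 1`.
#' @param seed Master seed; per-replicate seeds are derived from it so the
#'   whole run is reproducible.
#' @param null_model Simulate under the no-effect null (`beta1 = beta3 = 0`)
#'   for type-I-error estimation.
#' @param recruitment_mode `"sequential"` draws candidates until the enrolled
#'   target is met, so screening counts (and cost) are random, as in a real
#'   trial; `"fixed_sizes"` draws exactly the designed integer prescreen and
#'   screen totals.
#' @param normal_critical Compare the test statistic with the normal critical
#'   value used by the power approximation instead of the Welch t quantile.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(replicates = 10000, seed = 1L,
                            null_model = FALSE,
                            recruitment_mode = c("sequential", "fixed_sizes"),
                            normal_critical = FALSE) {
  check_number(replicates, "replicates", positive = TRUE)
  check_number(seed, "seed")
  structure(list(replicates = as.integer(replicates), seed = as.integer(seed),
                 null_model = isTRUE(null_model),
                 recruitment_mode = match.arg(recruitment_mode),
                 normal_critical = isTRUE(normal_critical)),
            class = "simulation_spec")
}

#' Draw candidate screening pairs
#'
#' Samples `m` correlated `(Z, X)` pairs from a [screening_model()] via the
#' conditional decomposition `Z ~ N(mu_z, sd_z^2)`,
#' `X | Z ~ N(mu_x + rho * sd_x/sd_z * (Z - mu_z), sd_x^2 (1 - rho^2))`.
#'
#' @param m Number of candidates.
#' @param screening A [screening_model()].
#' @param seed Optional seed; `NULL` uses the current RNG state.
#' @return A data.frame with columns `z` and `x`.
#' @export
simulate_candidates <- function(m, screening, seed = NULL) {
  stopifnot(inherits(screening, "screening_model"), m >= 1)
  if (!is.null(seed)) set.seed(seed)
  z <- stats::rnorm(m, screening$mu_z, screening$sd_z)
  x <- stats::rnorm(m,
                    screening$mu_x + screening$rho * screening$sd_x /
                      screening$sd_z * (z - screening$mu_z),
                    screening$sd_x * sqrt(1 - screening$rho^2))
  data.frame(z = z, x = x)
}

# Welch two-sample statistic with Satterthwaite df; y1 control, y2 treated.
welch_test <- function(y1, y2, alpha, normal_critical) {
  n1 <- length(y1); n2 <- length(y2)
  v1 <- stats::var(y1) / n1; v2 <- stats::var(y2) / n2
  tstat <- (mean(y2) - mean(y1)) / sqrt(v1 + v2)
  crit <- if (normal_critical) stats::qnorm(1 - alpha / 2) else {
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
    stats::qt(1 - alpha / 2, df)
  }
  list(statistic = tstat, reject = abs(tstat) > crit,
       estimate = mean(y2) - mean(y1))
}

# Recruit candidates through the (pre)screening cuts. Returns enrollee
# severities plus realized pipeline counts. b = -Inf gives one-stage
# behaviour (every candidate screened on X directly).
recruit <- function(n_target, a, b, screening, mode, fixed = NULL) {
  if (mode == "fixed_sizes") {
    cand <- simulate_candidates(fixed$prescreened, screening)
    screened <- cand[cand$z >= b, , drop = FALSE]
    enrolled <- screened[screened$x >= a, , drop = FALSE]
    return(list(x = enrolled$x, prescreened = fixed$prescreened,
                screened = nrow(screened), enrolled = nrow(enrolled)))
  }
  xs <- numeric(0)
  prescreened <- 0L; screened <- 0L
  p_pass <- joint_upper(screening, a, b)
  repeat {
    need <- n_target - length(xs)
    if (need <= 0L) break
    chunk <- max(64L, ceiling(1.25 * need / max(p_pass, 1e-6)))
    if (prescreened + chunk > .CANDIDATE_CAP)
      stop_enrichcost("candidate budget exhausted during recruitment",
                      "enrichcost_recruitment_failure")
    cand <- simulate_candidates(chunk, screening)
    pass_z <- cand$z >= b
    pass <- pass_z & cand$x >= a
    k <- cumsum(pass)
    if (k[chunk] >= need) {
      stop_at <- which(k == need)[1]  # stop at the candidate completing enrollment
      prescreened <- prescreened + stop_at
      screened <- screened + sum(pass_z[seq_len(stop_at)])
      xs <- c(xs, cand$x[seq_len(stop_at)][pass[seq_len(stop_at)]])
      break
    }
    prescreened <- prescreened + chunk
    screened <- screened + sum(pass_z)
    xs <- c(xs, cand$x[pass])
  }
  list(x = xs, prescreened = prescreened, screened = screened,
       enrolled = length(xs))
}

#' Simulate one trial at a designed configuration
#'
#' Runs the full pipeline once: recruit candidates through the design's
#' cut-offs until the enrolled total is met (or draw the designed fixed
#' sizes), randomize 1:1, generate outcomes from the interaction model, and
#' apply the two-sample test.
#'
#' @param design A `onestage_design` or `twostage_design`.
#' @param sim A [simulation_spec()]; its `null_model` flag replaces
#'   `beta1`/`beta3` with 0.
#' @param seed Optional seed for this replicate.
#' @return A list: `reject` (logical), `realized_cost`, `lambda_hat` (arm
#'   mean difference), `statistic`, and the realized pipeline `counts`.
#' @export
run_trial <- function(design, sim = simulation_spec(), seed = NULL) {
  stopifnot(inherits(design, c("onestage_design", "twostage_design")))
  if (!is.null(seed)) set.seed(seed)
  inp <- design$inputs
  out <- inp$outcome
  if (sim$null_model)
    out <- outcome_model(beta0 = out$beta0, beta1 = 0, beta2 = out$beta2,
                         beta3 = 0, sigma = out$sigma)
  two <- inherits(design, "twostage_design")
  b <- if (two) design$b_opt else -Inf
  if (design$n_total < 4L)
    stop_enrichcost("design must enroll at least 2 subjects per arm",
                    "enrichcost_invalid_parameter")
  fixed <- if (two) list(prescreened = design$M_total)
           else list(prescreened = design$N_total)
  rec <- recruit(design$n_total, design$a_opt, b, inp$screening,
                 sim$recruitment_mode, fixed)
  n <- rec$enrolled
  if (n < 4L)
    stop_enrichcost("fewer than 2 enrollees per arm were recruited",
                    "enrichcost_recruitment_failure")
  trt <- sample(rep(c(0L, 1L), length.out = n))
  y <- out$beta0 + out$beta1 * trt + out$beta2 * rec$x +
    out$beta3 * trt * rec$x + stats::rnorm(n, 0, out$sigma)
  tst <- welch_test(y[trt == 0L], y[trt == 1L], inp$test$alpha,
                    sim$normal_critical)
  cst <- inp$costs
  cost <- cst$c_trt * sum(trt == 1L) + cst$c_placebo * sum(trt == 0L) +
    if (two) cst$c_scr * rec$screened + cst$c_pre * rec$prescreened
    else cst$c_rec * rec$prescreened
  list(reject = tst$reject, realized_cost = cost,
       lambda_hat = tst$estimate, statistic = tst$statistic,
       counts = c(prescreened = rec$prescreened, screened = rec$screened,
                  enrolled = n))
}

#' Operating characteristics of a design by Monte Carlo
#'
#' Repeats [run_trial()] over seeded replicates under the design's effect
#' model (for power, realized cost and the average estimated arm difference)
#' and under the no-effect null (for type-I error), and aggregates.
#'
#' @param design A `onestage_design` or `twostage_design`.
#' @param sim A [simulation_spec()]; `replicates` and `seed` control both
#'   sweeps.
#' @return An object of class `simulation_summary`: `empirical_power`,
#'   `empirical_size`, their Monte-Carlo standard errors, `mean_cost`,
#'   `sd_cost`, `mean_lambda_hat`, `replicates_used`, and `seed`.
#' @export
estimate_operating_characteristics <- function(design,
                                               sim = simulation_spec()) {
  stopifnot(inherits(sim, "simulation_spec"))
  R <- sim$replicates
  set.seed(sim$seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2L * R), ncol = 2L)
  alt <- sim; alt$null_model <- FALSE
  nul <- sim; nul$null_model <- TRUE

  rejects <- logical(R); costs <- numeric(R); lams <- numeric(R)
  null_rejects <- logical(R)
  failures <- 0L
  for (i in seq_len(R)) {
    r <- tryCatch(run_trial(design, alt, seed = seeds[i, 1L]),
                  enrichcost_recruitment_failure = function(e) NULL)
    if (is.null(r)) { failures <- failures + 1L; rejects[i] <- NA } else {
      rejects[i] <- r$reject; costs[i] <- r$realized_cost
      lams[i] <- r$lambda_hat
    }
    rn <- tryCatch(run_trial(design, nul, seed = seeds[i, 2L]),
                   enrichcost_recruitment_failure = function(e) NULL)
    null_rejects[i] <- if (is.null(rn)) NA else rn$reject
  }
  ok <- !is.na(rejects)
  pw <- mean(rejects[ok]); sz <- mean(null_rejects, na.rm = TRUE)
  structure(list(
    empirical_power = pw,
    power_se = sqrt(pw * (1 - pw) / sum(ok)),
    empirical_size = sz,
    size_se = sqrt(sz * (1 - sz) / sum(!is.na(null_rejects))),
    mean_cost = mean(costs[ok]), sd_cost = stats::sd(costs[ok]),
    mean_lambda_hat = mean(lams[ok]),
    replicates_used = sum(ok), recruitment_failures = failures,
    seed = sim$seed),
    class = "simulation_summary")
}

#' @export
print.simulation_summary <- function(x, ...) {
  cat("Monte-Carlo operating characteristics\n")
  cat(sprintf("  replicates: %d (seed %d)\n", x$replicates_used, x$seed))
  cat(sprintf("  empirical power: %.3f (MC SE %.4f)\n",
              x$empirical_power, x$power_se))
  cat(sprintf("  empirical type-I error: %.3f (MC SE %.4f)\n",
              x$empirical_size, x$size_se))
  cat(sprintf("  realized cost: mean %.0f, SD %.0f\n", x$mean_cost, x$sd_cost))
  cat(sprintf("  mean estimated arm difference: %.3f\n", x$mean_lambda_hat))
  invisible(x)
}
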