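# Run configuration: YAML/JSON parsing with strict schema validation,
# default filling (echoed so a run is reconstructible from its log), and
# flat serialization of design records.

.CONFIG_SECTIONS <- list(
  outcome  = c("beta0", "beta1", "beta2", "beta3", "sigma"),
  screening = c("mu_x", "sd_x", "mu_z", "sd_z", "rho"),
  costs    = c("c_trt", "c_placebo", "c_rec", "c_scr", "c_pre", "currency"),
  test     = c("alpha", "target_power", "use_z_critical"),
  grid     = c("a_lo", "a_hi", "a_step", "b_lo", "b_hi", "b_step", "refine"),
  sim      = c("replicates", "seed", "null_model", "recruitment_mode",
               "normal_critical")
)

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) configuration into a fully validated `run_config`:
#' an [outcome_model()], [screening_model()], [cost_structure()],
#' [test_spec()], [grid_spec()] and optional [simulation_spec()]. Unknown
#' sections or keys are an error (listed by name); omitted optional values
#' get the documented defaults, echoed via `message()` so a run can be
#' reconstructed from its log.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file. Required sections:
#'   `outcome` (`beta1`, `beta3`, `sigma`; `beta0`, `beta2` default 0 and 1)
#'   and `screening` (`mu_x`, `sd_x`; `mu_z`, `sd_z` default to the `X`
#'   marginal, `rho` to 0). `costs`, `test`, `grid` and `sim` are optional.
#' @param quiet Suppress the default-echo messages.
#' @return An object of class `run_config` with elements `outcome`,
#'   `screening`, `costs`, `test`, `grid`, `sim`.
#' @examples
#' cfg <- load_config(system.file("extdata", "worked_example.yaml",
#'                                package = "enrichcost"), quiet = TRUE)
#' cfg$outcome
#' @export
load_config <- function(path, quiet = FALSE) {
  if (!file.exists(path))
    stop_enrichcost(sprintf("config file not found: %s", path),
                    "enrichcost_io_error")
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.list(raw))
    stop_enrichcost("config must parse to a mapping of sections",
                    "enrichcost_schema_error")

  bad_sections <- setdiff(names(raw), names(.CONFIG_SECTIONS))
  if (length(bad_sections))
    stop_enrichcost(paste0("unknown config section(s): ",
                           paste(bad_sections, collapse = ", ")),
                    "enrichcost_schema_error")
  for (sec in names(raw)) {
    bad <- setdiff(names(raw[[sec]]), .CONFIG_SECTIONS[[sec]])
    if (length(bad))
      stop_enrichcost(sprintf("unknown key(s) in `%s`: %s", sec,
                              paste(bad, collapse = ", ")),
                      "enrichcost_schema_error")
  }
  for (sec in c("outcome", "screening"))
    if (is.null(raw[[sec]]))
      stop_enrichcost(sprintf("config is missing required section `%s`", sec),
                      "enrichcost_schema_error")

  note <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  grab <- function(sec, key, default = NULL) {
    v <- raw[[sec]][[key]]
    if (is.null(v)) {
      if (!is.null(default))
        note("config: `%s.%s` defaulting to %s", sec, key,
             paste(format(default), collapse = " "))
      default
    } else v
  }

  o <- raw$outcome
  for (k in c("beta1", "beta3", "sigma"))
    if (is.null(o[[k]]))
      stop_enrichcost(sprintf("`outcome.%s` is required", k),
                      "enrichcost_schema_error")
  outcome <- tryCatch(
    outcome_model(beta0 = grab("outcome", "beta0", 0),
                  beta1 = o$beta1,
                  beta2 = grab("outcome", "beta2", 1),
                  beta3 = o$beta3, sigma = o$sigma),
    enrichcost_error = function(e)
      stop_enrichcost(paste0("outcome: ", conditionMessage(e)),
                      "enrichcost_validation_error"))

  s <- raw$screening
  for (k in c("mu_x", "sd_x"))
    if (is.null(s[[k]]))
      stop_enrichcost(sprintf("`screening.%s` is required", k),
                      "enrichcost_schema_error")
  screening <- tryCatch(
    screening_model(mu_x = s$mu_x, sd_x = s$sd_x,
                    mu_z = grab("screening", "mu_z", s$mu_x),
                    sd_z = grab("screening", "sd_z", s$sd_x),
                    rho = grab("screening", "rho", 0)),
    enrichcost_error = function(e)
      stop_enrichcost(paste0("screening: ", conditionMessage(e)),
                      "enrichcost_validation_error"))

  costs <- if (is.null(raw$costs)) NULL else
    cost_structure(c_trt = raw$costs$c_trt,
                   c_placebo = grab("costs", "c_placebo", raw$costs$c_trt),
                   c_rec = grab("costs", "c_rec", NA_real_),
                   c_scr = grab("costs", "c_scr", NA_real_),
                   c_pre = grab("costs", "c_pre", NA_real_),
                   currency = grab("costs", "currency", "USD"))

  test <- test_spec(alpha = grab("test", "alpha", 0.05),
                    target_power = grab("test", "target_power", 0.90),
                    use_z_critical = grab("test", "use_z_critical", TRUE))

  grid <- if (is.null(raw$grid)) {
    note("config: `grid` defaulting to mean +/- 3 SD, step 0.1")
    default_grid(screening)
  } else {
    dg <- default_grid(screening)
    grid_spec(a_lo = grab("grid", "a_lo", dg$a_lo),
              a_hi = grab("grid", "a_hi", dg$a_hi),
              a_step = grab("grid", "a_step", 0.1),
              b_lo = grab("grid", "b_lo", dg$b_lo),
              b_hi = grab("grid", "b_hi", dg$b_hi),
              b_step = grab("grid", "b_step", 0.1),
              refine = grab("grid", "refine", FALSE))
  }

  sim <- if (is.null(raw$sim)) NULL else
    simulation_spec(replicates = grab("sim", "replicates", 10000),
                    seed = grab("sim", "seed", 1L),
                    null_model = grab("sim", "null_model", FALSE),
                    recruitment_mode = grab("sim", "recruitment_mode",
                                            "sequential"),
                    normal_critical = grab("sim", "normal_critical", FALSE))

  structure(list(outcome = outcome, screening = screening, costs = costs,
                 test = test, grid = grid, sim = sim),
            class = "run_config")
}

#' The worked hot-flash example configuration
#'
#' The running example used throughout the documentation: baseline hot-flash
#' severity `X ~ N(5, 2^2)` on a 0-10 scale, surrogate `Z` with the same
#' marginal and correlation 0.7, outcome coefficients
#' `beta = (0, -0.2, 1, -0.25)` with `sigma = 2.5`, and unit costs
#' treatment/placebo $700, one-stage recruitment $300 (split $200 screening +
#' $100 prescreening in two-stage designs), at two-sided `alpha = 0.05` and
#' 90% power.
#'
#' @param rho Surrogate correlation, default 0.7.
#' @return A `run_config` (see [load_config()]).
#' @export
worked_example_config <- function(rho = 0.7) {
  screening <- screening_model(mu_x = 5, sd_x = 2, rho = rho)
  list_cfg <- list(
    outcome = outcome_model(beta1 = -0.2, beta3 = -0.25, sigma = 2.5),
    screening = screening,
    costs = cost_structure(c_trt = 700, c_placebo = 700, c_rec = 300,
                           c_scr = 200, c_pre = 100),
    test = test_spec(alpha = 0.05, target_power = 0.90),
    grid = default_grid(screening),
    sim = NULL)
  structure(list_cfg, class = "run_config")
}

# Flatten a design object to a one-row record of scalars.
design_record <- function(design) {
  keep <- intersect(
    c("a_opt", "b_opt", "n_star", "N_star", "M_star", "n_total", "N_total",
      "M_total", "cost_unrounded", "cost_rounded", "saving_abs", "saving_pct",
      "lambda1", "power_achieved"),
    names(design))
  rec <- design[keep]
  rec$currency <- design$inputs$costs$currency
  as.data.frame(rec)
}

#' Write a design record to JSON and CSV
#'
#' Serializes the flat scalar record of a design at full float precision
#' (`digits = NA`), so re-reading the JSON reproduces the in-memory values
#' exactly.
#'
#' @param design A `onestage_design` or `twostage_design`.
#' @param json_path,csv_path Output paths; either may be `NULL` to skip.
#' @return The record data.frame, invisibly.
#' @export
write_design <- function(design, json_path = NULL, csv_path = NULL) {
  rec <- design_record(design)
  if (!is.null(json_path))
    jsonlite::write_json(as.list(rec), json_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  if (!is.null(csv_path))
    utils::write.csv(rec, csv_path, row.names = FALSE)
  invisible(rec)
}

#' Regenerate the worked example end to end
#'
#' Reruns the whole analysis on the worked hot-flash example and writes
#' plot-ready tables: the one-stage threshold sweep (cost and sample-size
#' curves), the one-stage screening-share sweep, the two-stage versus
#' one-stage comparison profile, the prescreen-share and correlation sweeps,
#' and a summary table with calculated and (optionally) simulated columns,
#' plus a JSON of headline numbers. With the same `seed` the outputs are
#' reproducible.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed for the simulated columns.
#' @param replicates Monte-Carlo replicates per summary row; 0 skips the
#'   simulated columns entirely.
#' @param shares,rhos Sweep grids for the prescreen-share and correlation
#'   tables.
#' @return Invisibly, the headline list written to `summary.json`.
#' @export
reproduce_worked_example <- function(out_dir, seed = 1L, replicates = 0,
                                     shares = c(0.10, 0.20, 0.30, 0.40, 0.50),
                                     rhos = c(0.30, 0.45, 0.60, 0.75, 0.90)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- worked_example_config()
  p <- function(f) file.path(out_dir, f)

  one <- optimize_onestage(cfg$outcome, cfg$screening, cfg$costs, cfg$test,
                           cfg$grid, keep_grid = TRUE)
  utils::write.csv(one$grid, p("onestage_threshold_sweep.csv"),
                   row.names = FALSE)

  share1 <- sweep_screening_share(seq(0.1, 0.9, by = 0.1), cfg$outcome,
                                  cfg$screening, cfg$test, grid = cfg$grid)
  utils::write.csv(share1, p("onestage_screening_share_sweep.csv"),
                   row.names = FALSE)

  two <- optimize_twostage(cfg$outcome, cfg$screening, cfg$costs, cfg$test,
                           cfg$grid, keep_grid = TRUE)
  utils::write.csv(two$grid, p("twostage_threshold_profile.csv"),
                   row.names = FALSE)

  share2 <- sweep_prescreen_share(shares, cfg$outcome, cfg$screening,
                                  cfg$test, grid = cfg$grid)
  utils::write.csv(share2, p("twostage_prescreen_share_sweep.csv"),
                   row.names = FALSE)
  rho2 <- sweep_rho(rhos, cfg$outcome, cfg$screening, cfg$costs, cfg$test,
                    cfg$grid)
  utils::write.csv(rho2, p("twostage_rho_sweep.csv"), row.names = FALSE)

  summary_tab <- data.frame(
    share = share2$share, rho = cfg$screening$rho,
    calc_onestage_k = one$cost_unrounded / 1000,
    calc_twostage_k = share2$cost_unrounded / 1000)
  if (replicates > 0) {
    sim_cols <- lapply(seq_len(nrow(share2)), function(i) {
      cst <- cost_structure(c_trt = cfg$costs$c_trt,
                            c_placebo = cfg$costs$c_placebo,
                            c_scr = share2$c_scr[i], c_pre = share2$c_pre[i])
      d <- optimize_twostage(cfg$outcome, cfg$screening, cst, cfg$test,
                             cfg$grid)
      s <- estimate_operating_characteristics(
        d, simulation_spec(replicates = replicates, seed = seed + i))
      data.frame(sim_twostage_k = s$mean_cost / 1000,
                 sim_power = s$empirical_power,
                 sim_type1 = s$empirical_size)
    })
    summary_tab <- cbind(summary_tab, do.call(rbind, sim_cols))
  }
  utils::write.csv(summary_tab, p("summary_table.csv"), row.names = FALSE)

  headline <- list(
    onestage_a_opt = one$a_opt,
    onestage_cost_rounded = one$cost_rounded,
    onestage_cost_unrounded = one$cost_unrounded,
    onestage_totals = c(screened = one$N_total, enrolled = one$n_total),
    twostage_a_opt = two$a_opt, twostage_b_opt = two$b_opt,
    twostage_cost_rounded = two$cost_rounded,
    twostage_totals = c(prescreened = two$M_total, screened = two$N_total,
                        enrolled = two$n_total),
    saving_abs = two$saving_abs, saving_pct = two$saving_pct,
    seed = seed)
  jsonlite::write_json(headline, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(headline)
}
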