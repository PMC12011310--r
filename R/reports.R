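#' Measure-wise MSE ratio table
#'
#' Computes the combined-over-separated MSE ratios for fixed effects, random
#' effects (all, intercept only, slope only) and predicted values, overall
#' and per measure, in the layout of a case-study summary table.
#'
#' @param subjects list of `subject_design`.
#' @param true_components true (combined) `covariance_components`.
#' @param beta_known treat the fixed effects as known when evaluating random
#'   effects and predictions.
#' @return data.frame with columns `estimand`, `selection`, `measure`,
#'   `ratio`.
#' @export
measure_ratio_table <- function(subjects, true_components, beta_known = TRUE) {
  if (inherits(subjects, "subject_design")) subjects <- list(subjects)
  measures <- vapply(subjects[[1]]$markers, `[[`, character(1), "measure_id")
  rows <- list()
  add <- function(estimand, selection, measure, ratio)
    rows[[length(rows) + 1L]] <<- data.frame(
      estimand = estimand, selection = selection, measure = measure,
      ratio = ratio, stringsAsFactors = FALSE)

  fC <- fixed_effects_mse(subjects, true_components, "combined")
  fS <- fixed_effects_mse(subjects, true_components, "separated")
  add("beta", "all", "overall", mse_ratio(fC, fS))
  for (k in measures)
    add("beta", "all", k, mse_ratio(fC, fS, measure = k))

  bC <- random_effects_mse(subjects, true_components, "combined", beta_known)
  bS <- random_effects_mse(subjects, true_components, "separated", beta_known)
  add("b", "all", "overall", mse_ratio(bC, bS))
  for (k in measures) {
    add("b", "all", k, mse_ratio(bC, bS, measure = k))
    add("b", "intercept", k, mse_ratio(bC, bS, measure = k, effect = "intercept"))
    add("b", "slope", k, mse_ratio(bC, bS, measure = k, effect = "slope"))
  }

  yC <- predicted_values_mse(subjects, true_components, "combined", beta_known)
  yS <- predicted_values_mse(subjects, true_components, "separated", beta_known)
  add("y", "all", "overall", mse_ratio(yC, yS))
  for (k in measures)
    add("y", "all", k, mse_ratio(yC, yS, measure = k))

  do.call(rbind, rows)
}

#' Write covariance components as labelled CSV matrices
#'
#' @param components a `covariance_components`.
#' @param d_path,r_path output CSV paths for D and R (row/column labels
#'   `"measure:effect"` and measure names respectively).
#' @export
write_components_csv <- function(components, d_path, r_path) {
  stopifnot(inherits(components, "covariance_components"))
  utils::write.csv(components$D, d_path, row.names = TRUE)
  utils::write.csv(components$R, r_path, row.names = TRUE)
  invisible(c(d_path, r_path))
}

#' Read covariance components from labelled CSV matrices
#'
#' @param d_path,r_path CSV paths written by [write_components_csv()].
#' @param q random effects per measure (inferred as equal split by default).
#' @return a `covariance_components`.
#' @export
read_components_csv <- function(d_path, r_path, q = NULL) {
  D <- as.matrix(utils::read.csv(d_path, row.names = 1, check.names = FALSE))
  R <- as.matrix(utils::read.csv(r_path, row.names = 1, check.names = FALSE))
  covariance_components(D, R, q = q)
}

run_manifest <- function(dir, config) {
  manifest <- list(created = format(Sys.time(), tz = "UTC", usetz = TRUE),
                   package_version = as.character(utils::packageVersion("mlmmeff")),
                   config = config)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the bivariate grid study and write tidy artifacts
#'
#' Writes `grid_results.csv` (one row per cell), `grid_summary.csv`
#' (five-number summaries over likely cells) and `heatmap_long.csv`
#' (correlation-plane table), plus a JSON manifest recording the
#' configuration and seeds.
#'
#' @param out_dir output directory (created if needed).
#' @param spec grid specification (default full paper-style grid).
#' @param n_pattern_draws seeded random-pattern draws per stochastic cell.
#' @param base_seed integer seed.
#' @return the grid results data.frame, invisibly.
#' @export
run_grid_report <- function(out_dir, spec = default_grid_spec(),
                            n_pattern_draws = 20, base_seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- run_grid(spec, n_pattern_draws, base_seed)
  utils::write.csv(res, file.path(out_dir, "grid_results.csv"),
                   row.names = FALSE)
  utils::write.csv(summarize_grid(res),
                   file.path(out_dir, "grid_summary.csv"), row.names = FALSE)
  utils::write.csv(heatmap_long(res),
                   file.path(out_dir, "heatmap_long.csv"), row.names = FALSE)
  run_manifest(out_dir, list(subcommand = "grid", base_seed = base_seed,
                             n_pattern_draws = n_pattern_draws,
                             n_cells = nrow(spec)))
  invisible(res)
}

#' Generate a synthetic cohort and write it as CSV
#'
#' Writes `cohort.csv` (long format), `covariates.csv`, the true components
#' as labelled CSVs, and a JSON manifest with the seed and spec summary.
#'
#' @param out_dir output directory.
#' @param m subjects.
#' @param seed integer seed.
#' @param spec optional full `cohort_spec` (overrides `m` and `seed`).
#' @return the `mlmm_cohort`, invisibly.
#' @export
run_cohort_report <- function(out_dir, m = 200, seed = 1L, spec = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(spec)) spec <- cohort_spec(m = m, seed = seed)
  cohort <- simulate_cohort(spec)
  utils::write.csv(cohort$data, file.path(out_dir, "cohort.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$covariates, file.path(out_dir, "covariates.csv"),
                   row.names = FALSE)
  write_components_csv(spec$components,
                       file.path(out_dir, "true_D.csv"),
                       file.path(out_dir, "true_R.csv"))
  run_manifest(out_dir, list(subcommand = "cohort", m = spec$m,
                             seed = spec$seed))
  invisible(cohort)
}

#' Estimate components from a cohort and write efficiency reports
#'
#' Runs the moment-based covariance estimation on a cohort, writes the
#' estimated components, the three yearly-correlation tables (empirical,
#' implied by the combined estimate, implied by its separated projection)
#' and the measure-wise MSE ratio table evaluated at the estimates.
#'
#' @param out_dir output directory.
#' @param cohort an `mlmm_cohort`.
#' @param n_subjects_ratio number of subjects used for the ratio table
#'   (caps compute; ratios are subject averages).
#' @return the `component_estimates`, invisibly.
#' @export
run_estimate_report <- function(out_dir, cohort, n_subjects_ratio = 200) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  est <- estimate_components(cohort)
  write_components_csv(est$components,
                       file.path(out_dir, "estimated_D.csv"),
                       file.path(out_dir, "estimated_R.csv"))
  utils::write.csv(empirical_yearly_correlation(cohort),
                   file.path(out_dir, "correlation_empirical.csv"))
  utils::write.csv(implied_yearly_correlation(est$components),
                   file.path(out_dir, "correlation_combined.csv"))
  utils::write.csv(
    implied_yearly_correlation(separate_components(est$components)),
    file.path(out_dir, "correlation_separated.csv"))
  subs <- cohort$subjects[seq_len(min(n_subjects_ratio,
                                      length(cohort$subjects)))]
  utils::write.csv(measure_ratio_table(subs, est$components),
                   file.path(out_dir, "ratio_table.csv"), row.names = FALSE)
  run_manifest(out_dir, list(subcommand = "estimate",
                             m = length(cohort$subjects),
                             n_subjects_ratio = length(subs)))
  invisible(est)
}

parse_cli_args <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      out[[key]] <- TRUE; i <- i + 1L
    } else {
      out[[key]] <- args[i + 1L]; i <- i + 2L
    }
  }
  out
}

cli_num <- function(opts, key, default) {
  if (is.null(opts[[key]])) default else as.numeric(opts[[key]])
}

#' Command-line entry point
#'
#' Dispatches the subcommands `grid`, `cohort`, `estimate`, `oracle` and
#' `report` used by the `inst/cli/mlmmeff` script. Arguments are
#' `--key value` pairs; every stochastic run takes a `--seed` and writes its
#' outputs plus a JSON manifest under `--out`.
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cat("usage: mlmmeff <grid|cohort|estimate|oracle> [--key value ...]\n")
    return(invisible(1L))
  }
  sub <- args[1]
  opts <- parse_cli_args(args[-1])
  out_dir <- if (is.null(opts$out)) "." else opts$out
  seed <- as.integer(cli_num(opts, "seed", 1))
  status <- 0L
  switch(sub,
    grid = {
      spec <- default_grid_spec(
        cases = if (is.null(opts$case)) c("A", "B", "C")
                else strsplit(opts$case, ",")[[1]],
        pmiss = if (is.null(opts$pmiss)) c(0, 1/3, 2/3)
                else as.numeric(strsplit(opts$pmiss, ",")[[1]]),
        pattern = if (is.null(opts$pattern)) "random" else opts$pattern)
      run_grid_report(out_dir, spec,
                      n_pattern_draws = cli_num(opts, "draws", 20),
                      base_seed = seed)
    },
    cohort = {
      run_cohort_report(out_dir, m = cli_num(opts, "m", 200), seed = seed)
    },
    estimate = {
      cohort <- if (!is.null(opts$cohort_dir)) {
        dat <- utils::read.csv(file.path(opts$cohort_dir, "cohort.csv"))
        cov <- utils::read.csv(file.path(opts$cohort_dir, "covariates.csv"))
        des <- build_cohort_design(dat, cov)
        structure(list(data = dat, covariates = cov,
                       subjects = des$subjects, knots = des$knots,
                       spec = cohort_spec(m = nrow(cov))),
                  class = "mlmm_cohort")
      } else {
        simulate_cohort(cohort_spec(m = cli_num(opts, "m", 200), seed = seed))
      }
      run_estimate_report(out_dir, cohort,
                          n_subjects_ratio = cli_num(opts, "subjects", 200))
    },
    oracle = {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      cfg <- random_config(seed, K = as.integer(cli_num(opts, "K", 2)),
                           m = as.integer(cli_num(opts, "m", 2)))
      reports <- list()
      for (est in c("beta", "b", "y")) for (w in c("combined", "separated")) {
        r <- empirical_mse(cfg$subjects, cfg$components, w, est,
                           beta_known = is.null(opts$estimated_beta),
                           n_reps = cli_num(opts, "reps", 1e4), seed = seed)
        reports[[paste(est, w, sep = "_")]] <-
          list(empirical = r$empirical, se = r$se, z = as.list(r$z),
               closed_form = list(mse = r$closed_form$mse,
                                  bias2 = r$closed_form$squared_bias,
                                  var = r$closed_form$variance))
      }
      jsonlite::write_json(reports, file.path(out_dir, "oracle_report.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      run_manifest(out_dir, list(subcommand = "oracle", seed = seed,
                                 reps = cli_num(opts, "reps", 1e4)))
    },
    {
      message("unknown subcommand: ", sub)
      status <- 1L
    })
  invisible(status)
}
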