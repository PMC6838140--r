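#' Write and read a cohort directory
#'
#' A cohort directory holds `trials.csv` (the trial-data dialect),
#' `ground_truth.csv` (subject, group, natural-scale generating
#' parameters) and `manifest.json` (seed, schedule length, group
#' definitions) — enough to regenerate the cohort bit-exactly.
#'
#' @param cohort A `gng_cohort`.
#' @param dir Directory path (created if missing).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` a
#'   `gng_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "gng_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_trials(cohort$trials, file.path(dir, "trials.csv"))
  readr::write_csv(cohort$ground_truth, file.path(dir, "ground_truth.csv"))
  jsonlite::write_json(cohort$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  structure(
    list(trials = read_trials(file.path(dir, "trials.csv")),
         ground_truth = readr::read_csv(file.path(dir, "ground_truth.csv"),
                                        show_col_types = FALSE),
         manifest = jsonlite::read_json(file.path(dir, "manifest.json"),
                                        simplifyVector = FALSE)),
    class = "gng_cohort"
  )
}

#' Pipeline commands
#'
#' End-to-end entry points binding the pipeline together; each writes its
#' outputs plus a manifest sufficient to reproduce them, and is what the
#' `pavlearn` command-line script (in `inst/scripts/`) dispatches to.
#'
#' * `run_simulate()`: generate a cohort and write the cohort directory.
#' * `run_fit()`: read a cohort's trials, fit one model spec
#'   hierarchically, write per-subject estimates (CSV) and
#'   hyperparameters + EM trace (JSON).
#' * `run_select()`: run the full stepwise selection and write the trace
#'   (JSON) and a human-readable candidate table (CSV).
#' * `run_recover()`: simulate, fit the generating spec, and write a
#'   parameter-recovery report (per-parameter bias, RMSE, and per-subject
#'   truth-vs-estimate pairs).
#'
#' @param out Output directory.
#' @param seed Integer seed.
#' @param groups Group presets for simulation (default
#'   [default_groups()]).
#' @param n_per_condition Trials per condition.
#' @param cohort_dir Directory holding `trials.csv`.
#' @param spec A `gng_spec` (or spec string) to fit.
#' @param config A `gng_fit_config`.
#' @return The principal result object, invisibly (`gng_cohort`,
#'   `gng_fit`, `gng_selection`, or the recovery report tibble).
#' @export
run_simulate <- function(out, seed = 1, groups = default_groups(),
                         n_per_condition = 60) {
  cohort <- generate_cohort(groups, n_per_condition = n_per_condition,
                            seed = seed)
  write_cohort(cohort, out)
  invisible(cohort)
}

#' @rdname run_simulate
#' @export
run_fit <- function(cohort_dir, out, spec = winning_spec(),
                    config = gng_fit_config(), seed = 1) {
  if (is.character(spec)) spec <- parse_spec(spec)
  trials <- read_trials(file.path(cohort_dir, "trials.csv"))
  fit <- em_fit(trials, spec, config = config, seed = seed)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(fit$subjects, file.path(out, "subject_params.csv"))
  jsonlite::write_json(
    list(spec = spec_string(spec), seed = seed,
         converged = fit$converged, iterations = fit$iterations,
         prior = list(mu = as.list(fit$prior$mu),
                      sigma2 = as.list(fit$prior$sigma2)),
         trace = lapply(seq_len(nrow(fit$trace)), function(i) list(
           iteration = fit$trace$iteration[i],
           evidence = fit$trace$evidence[i],
           max_change = fit$trace$max_change[i]))),
    file.path(out, "fit.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(fit)
}

#' @rdname run_simulate
#' @export
run_select <- function(cohort_dir, out, config = gng_fit_config(),
                       seed = 1) {
  trials <- read_trials(file.path(cohort_dir, "trials.csv"))
  sel <- stepwise_select(trials, seed = seed, config = config)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(sel$steps, file.path(out, "selection_table.csv"))
  jsonlite::write_json(
    list(seed = seed, winner = spec_string(sel$winner),
         winner_ibic = sel$winner_ibic$value,
         steps = lapply(seq_len(nrow(sel$steps)), function(i)
           as.list(sel$steps[i, ]))),
    file.path(out, "selection.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(sel)
}

#' @rdname run_simulate
#' @export
run_recover <- function(out, seed = 1, groups = default_groups(),
                        n_per_condition = 60, config = gng_fit_config()) {
  cohort <- generate_cohort(groups, n_per_condition = n_per_condition,
                            seed = seed)
  spec <- parse_spec(cohort$manifest$groups[[1]]$spec)
  fit <- em_fit(cohort$trials, spec, config = config, seed = seed)
  report <- recovery_report(cohort, fit)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$pairs, file.path(out, "recovery_pairs.csv"))
  readr::write_csv(report$summary, file.path(out, "recovery_summary.csv"))
  jsonlite::write_json(cohort$manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Parameter-recovery report
#'
#' Joins a cohort's generating parameters with a fit's per-subject
#' estimates and summarises recovery per parameter (and per group):
#' bias (mean estimate minus mean truth), RMSE, and the truth-estimate
#' correlation.
#'
#' @param cohort A `gng_cohort` with ground truth.
#' @param fit A `gng_fit` of the same trials.
#' @return A list with `pairs` (subject, group, parameter, truth,
#'   estimate) and `summary` (group, parameter, bias, rmse, cor).
#' @export
recovery_report <- function(cohort, fit) {
  nm <- param_names(fit$spec)
  truth <- tidyr::pivot_longer(cohort$ground_truth,
                               cols = tidyr::all_of(nm),
                               names_to = "parameter", values_to = "truth")
  est <- tidy(fit)[, c("subject", "parameter", "estimate")]
  pairs <- dplyr::inner_join(truth, est, by = c("subject", "parameter"))
  summary <- dplyr::summarise(
    dplyr::group_by(pairs, .data$group, .data$parameter),
    n = dplyr::n(),
    bias = mean(.data$estimate - .data$truth),
    rmse = sqrt(mean((.data$estimate - .data$truth)^2)),
    cor = suppressWarnings(stats::cor(.data$truth, .data$estimate)),
    mean_truth = mean(.data$truth),
    mean_estimate = mean(.data$estimate),
    .groups = "drop")
  list(pairs = pairs, summary = summary)
}
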