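#' Per-condition error rates
#'
#' An error is any trial whose action differs from the condition's correct
#' action (failing to go in go conditions, going in no-go conditions).
#' Rates are computed per condition and, if a `subject` column is present,
#' per subject.
#'
#' @param trials A trial tibble.
#' @return A tibble with columns (`subject`,) `condition`, `n_trials`,
#'   `n_errors`, `error_rate`. Errors if any subject is missing one of the
#'   four conditions.
#' @export
error_rates <- function(trials) {
  has_subject <- "subject" %in% names(trials)
  trials <- validate_trials(trials, require_subject = has_subject)
  trials$error <- trials$action != cond_correct_action(trials$condition)
  keys <- if (has_subject) c("subject", "condition") else "condition"
  out <- dplyr::summarise(
    dplyr::group_by(trials, dplyr::across(tidyr::all_of(keys))),
    n_trials = dplyr::n(), n_errors = sum(.data$error),
    error_rate = mean(.data$error), .groups = "drop")
  n_units <- if (has_subject) length(unique(out$subject)) else 1L
  if (nrow(out) != 4L * n_units) {
    abort("Every subject must have trials in all four conditions.")
  }
  out$condition <- factor(out$condition, levels = cond_levels())
  dplyr::arrange(out, dplyr::across(tidyr::all_of(keys)))
}

as_group_summary <- function(x, who) {
  if (is.data.frame(x)) x <- as.list(x)
  need <- c("n", "mean", "sd")
  if (!all(need %in% names(x))) {
    abort(paste0("Group summary ", who, " needs fields n, mean, sd."))
  }
  if (x$n < 2) abort(paste0("Group summary ", who, " needs n >= 2."))
  if (x$sd < 0) abort(paste0("Group summary ", who, " has negative sd."))
  x
}

#' Two-sample t statistics from summary statistics
#'
#' `pooled_t()` is the Student two-sample t with pooled variance (sample
#' SDs, n - 1 denominator) and df = n1 + n2 - 2; `welch_t()` is Welch's
#' unequal-variance t with the Welch-Satterthwaite df. Both take the two
#' groups as summaries (n, mean, sd) — the form printed in participant
#' tables — rather than raw data.
#'
#' @param a,b Group summaries: one-row data frames or named lists with
#'   fields `n`, `mean`, `sd`.
#' @return A one-row tibble with `t`, `df` and the two-sided `p_value`.
#'   If the pooled variance is zero with unequal means, `t` is signed
#'   infinite.
#' @export
#' @examples
#' pooled_t(list(n = 21, mean = 42.76, sd = 4.62),
#'          list(n = 22, mean = 25.64, sd = 2.44))   # t = 15.29
pooled_t <- function(a, b) {
  a <- as_group_summary(a, "a"); b <- as_group_summary(b, "b")
  df <- a$n + b$n - 2
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
  se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  t <- if (se == 0) {
    if (a$mean == b$mean) 0 else sign(a$mean - b$mean) * Inf
  } else (a$mean - b$mean) / se
  tibble::tibble(t = t, df = df, p_value = 2 * pt(-abs(t), df))
}

#' @rdname pooled_t
#' @export
welch_t <- function(a, b) {
  a <- as_group_summary(a, "a"); b <- as_group_summary(b, "b")
  va <- a$sd^2 / a$n
  vb <- b$sd^2 / b$n
  se <- sqrt(va + vb)
  if (se == 0) {
    t <- if (a$mean == b$mean) 0 else sign(a$mean - b$mean) * Inf
    df <- a$n + b$n - 2
  } else {
    t <- (a$mean - b$mean) / se
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  }
  tibble::tibble(t = t, df = df, p_value = 2 * pt(-abs(t), df))
}

#' Tidy long export of per-subject measures
#'
#' Combines per-subject error rates and (optionally) fitted parameters
#' into the long format `subject, group, measure, value`, suitable for
#' downstream ANOVA/regression in external software.
#'
#' @param trials A multi-subject trial tibble.
#' @param fit Optional `gng_fit` whose per-subject estimates are appended.
#' @param groups Optional tibble `subject, group` (e.g. a cohort's
#'   ground truth); otherwise `group` is `NA`.
#' @return A tibble `subject, group, measure, value`.
#' @export
subject_measures <- function(trials, fit = NULL, groups = NULL) {
  er <- error_rates(trials)
  if (!"subject" %in% names(er)) abort("`trials` must have a subject column.")
  long <- tibble::tibble(
    subject = er$subject,
    measure = paste0("error_rate_", er$condition),
    value = er$error_rate)
  if (!is.null(fit)) {
    td <- tidy(fit)
    long <- dplyr::bind_rows(long, tibble::tibble(
      subject = td$subject, measure = td$parameter, value = td$estimate))
  }
  if (!is.null(groups)) {
    long <- dplyr::left_join(long, groups[, c("subject", "group")],
                             by = "subject")
  } else {
    long$group <- NA_character_
  }
  long[, c("subject", "group", "measure", "value")]
}
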