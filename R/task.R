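#' The four task conditions
#'
#' The go/no-go gain-loss task crosses the required action (go vs. no-go)
#' with the outcome domain (gain attainment vs. loss avoidance), giving four
#' conditions. Gain-domain trials pay +1 (reward) or 0; loss-domain trials
#' pay 0 or -1 (punishment). The coded outcome unit absorbs the monetary
#' stake (one coin per trial), so outcomes live in \{-1, 0, +1\}.
#'
#' @return A tibble with columns `condition`, `domain` ("gain"/"loss") and
#'   `correct_action` ("go"/"nogo"), one row per condition.
#' @export
#' @examples
#' gng_conditions()
gng_conditions <- function() {
  tibble::tibble(
    condition      = cond_levels(),
    domain         = c("gain", "gain", "loss", "loss"),
    correct_action = c("go", "nogo", "go", "nogo")
  )
}

cond_levels <- function() c("go_gain", "nogo_gain", "go_avoid", "nogo_avoid")

cond_code <- function(condition) {
  code <- match(condition, cond_levels())
  if (anyNA(code)) {
    bad <- unique(condition[is.na(code)])
    abort(paste0("Unknown condition label(s): ", paste(bad, collapse = ", ")))
  }
  code
}

cond_domain <- function(condition) {
  ifelse(cond_code(condition) <= 2L, "gain", "loss")
}

cond_correct_action <- function(condition) {
  c("go", "nogo", "go", "nogo")[cond_code(condition)]
}

action_code <- function(action) {
  code <- match(action, c("nogo", "go")) - 1L
  if (anyNA(code)) {
    bad <- unique(action[is.na(code)])
    abort(paste0("Unknown action label(s): ", paste(bad, collapse = ", ")))
  }
  code
}

#' Generate a block-randomized trial schedule
#'
#' Builds a schedule in which each consecutive block of four trials contains
#' all four conditions exactly once, in an independently randomized order
#' per block. With the default `n_per_condition = 60` this yields the full
#' 240-trial session of the task design.
#'
#' @param n_per_condition Number of trials per condition (>= 1).
#' @param seed Optional integer seed; schedules are reproducible
#'   bit-for-bit given the same seed. `NULL` uses the current RNG state.
#' @return A tibble with columns `trial` (1-based index) and `condition`.
#' @export
#' @examples
#' generate_schedule(n_per_condition = 2, seed = 1)
generate_schedule <- function(n_per_condition = 60, seed = NULL) {
  if (!is.numeric(n_per_condition) || length(n_per_condition) != 1 ||
      is.na(n_per_condition) || n_per_condition < 1 ||
      n_per_condition != round(n_per_condition)) {
    abort("`n_per_condition` must be a positive integer.")
  }
  n_per_condition <- as.integer(n_per_condition)
  conds <- with_seed(seed, {
    blocks <- replicate(n_per_condition, sample.int(4L), simplify = FALSE)
    cond_levels()[unlist(blocks)]
  })
  tibble::tibble(trial = seq_along(conds), condition = conds)
}

#' Sample probabilistic trial outcomes
#'
#' Implements the 80/20 feedback contingency: the correct action for a
#' condition yields the domain's better outcome (+1 in gain, 0 in loss)
#' with probability 0.8 and the worse outcome (0 in gain, -1 in loss) with
#' probability 0.2; the incorrect action reverses the probabilities.
#' Gain-domain trials never pay -1 and loss-domain trials never pay +1.
#'
#' @param condition Character vector of condition labels.
#' @param action Character vector ("go"/"nogo"), recycled against
#'   `condition`.
#' @param seed Optional integer seed.
#' @return Integer vector of outcomes in \{-1, 0, 1\}.
#' @export
#' @examples
#' table(sample_outcomes(rep("go_gain", 1000), "go", seed = 1))
sample_outcomes <- function(condition, action, seed = NULL) {
  n <- max(length(condition), length(action))
  condition <- rep_len(condition, n)
  action <- rep_len(action, n)
  correct <- action == cond_correct_action(condition)
  loss <- cond_domain(condition) == "loss"
  p_better <- ifelse(correct, 0.8, 0.2)
  better <- with_seed(seed, runif(n) < p_better)
  out <- integer(n)
  out[loss & !better] <- -1L      # punishment delivered
  out[!loss & better] <- 1L       # reward delivered
  out                             # otherwise 0 (no gain / no loss)
}

# Validate a trial table against the CSV dialect and domain-support rules.
# Returns the table with canonical column order; errors carry row numbers.
validate_trials <- function(trials, require_subject = TRUE) {
  required <- c("trial", "condition", "action", "outcome")
  if (require_subject) required <- c("subject", required)
  missing_cols <- setdiff(required, names(trials))
  if (length(missing_cols) > 0) {
    abort(paste0("Trial data is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  cond_code(trials$condition)
  action_code(trials$action)
  if (!all(trials$outcome %in% c(-1L, 0L, 1L))) {
    bad <- which(!(trials$outcome %in% c(-1L, 0L, 1L)))
    abort(paste0("Outcomes outside {-1, 0, 1} at row(s): ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  loss <- cond_domain(trials$condition) == "loss"
  bad <- which((!loss & trials$outcome == -1L) | (loss & trials$outcome == 1L))
  if (length(bad) > 0) {
    abort(paste0("Outcome outside the condition's domain support at row(s): ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  trials[required]
}

# Split a (possibly multi-subject) trial table into per-subject integer
# encodings consumed by the C++ likelihood core.
split_sessions <- function(trials) {
  trials <- validate_trials(trials, require_subject = "subject" %in% names(trials))
  if (!"subject" %in% names(trials)) trials$subject <- "s1"
  trials <- dplyr::arrange(trials, .data$subject, .data$trial)
  lapply(split(trials, trials$subject), function(d) {
    list(cond = cond_code(d$condition),
         act  = action_code(d$action),
         out  = as.integer(d$outcome))
  })
}

#' Read and write trial data CSV
#'
#' The on-disk dialect has header `subject,trial,condition,action,outcome`
#' with `condition` in go_gain/nogo_gain/go_avoid/nogo_avoid, `action` in
#' go/nogo and `outcome` in -1/0/1. Reading validates the schema (errors
#' name the offending column or rows) and writing round-trips losslessly.
#'
#' @param path File path.
#' @param trials A trial tibble as produced by [simulate_agent()] or
#'   [generate_cohort()].
#' @return `read_trials()` returns a validated tibble; `write_trials()`
#'   returns `path` invisibly.
#' @export
read_trials <- function(path) {
  trials <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      subject = readr::col_character(),
      trial = readr::col_integer(),
      condition = readr::col_character(),
      action = readr::col_character(),
      outcome = readr::col_integer()
    )
  ))
  validate_trials(trials)
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  trials <- validate_trials(trials)
  readr::write_csv(trials, path)
  invisible(path)
}
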