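#' Integrated BIC by Monte-Carlo marginal likelihood
#'
#' Draws `k_samples` parameter vectors from the fitted population
#' distribution (transformed scale, mapped to the natural scale), computes
#' every subject's session likelihood under every draw, takes the log of
#' each subject's mean likelihood (log-sum-exp minus log k), sums over
#' subjects, and adds the parameter-count penalty:
#'
#'   iBIC = -2 * sum_j log( mean_k p(choices_j | theta_k) ) + |M| log(n)
#'
#' where n is the total number of choices in the cohort and |M| counts the
#' population-level free parameters — by default two per model parameter
#' (a mean and a variance), configurable to one via `penalty_per_param`.
#' Smaller iBIC is better.
#'
#' @param trials A multi-subject trial tibble.
#' @param fit A `gng_fit` from [em_fit()] (supplies the spec and the
#'   fitted prior), or a `gng_prior`.
#' @param k_samples Number of Monte-Carlo draws (>= 2; default 1000).
#' @param seed Integer seed for the draws.
#' @param penalty_per_param 2 (default) or 1; see above.
#' @return An object of class `gng_ibic`: `value`, `log_marginal`,
#'   `n_params` (the penalty count |M|), `n_obs`, `k_samples`.
#' @export
ibic <- function(trials, fit, k_samples = 1000, seed = 1,
                 penalty_per_param = 2) {
  if (inherits(fit, "gng_fit")) prior <- fit$prior
  else if (inherits(fit, "gng_prior")) prior <- fit
  else abort("`fit` must be a gng_fit or gng_prior.")
  if (k_samples < 2) abort("`k_samples` must be at least 2.")
  stopifnot(penalty_per_param %in% c(1, 2))
  spec <- prior$spec
  cd <- spec_codes(spec)
  sessions <- split_sessions(trials)
  k <- length(prior$mu)

  theta_draws <- with_seed(seed, {
    matrix(rnorm(k_samples * k, mean = rep(prior$mu, each = k_samples),
                 sd = rep(sqrt(prior$sigma2), each = k_samples)),
           nrow = k_samples, ncol = k)
  })
  par_mat <- t(apply(theta_draws, 1, function(th) {
    cpp_expand_theta(th, cd$lr, cd$rho, cd$b, cd$p)
  }))

  log_marginal <- sum(vapply(sessions, function(s) {
    ll <- cpp_loglik_draws(s$cond, s$act, s$out, par_mat, cd$p == 1L)
    m <- max(ll)
    m + log(mean(exp(ll - m)))
  }, numeric(1)))

  n_obs <- sum(vapply(sessions, function(s) length(s$cond), 1L))
  n_pop <- penalty_per_param * n_params(spec)
  structure(
    list(value = -2 * log_marginal + n_pop * log(n_obs),
         log_marginal = log_marginal, n_params = n_pop, n_obs = n_obs,
         k_samples = k_samples, spec = spec),
    class = "gng_ibic"
  )
}

#' @export
print.gng_ibic <- function(x, ...) {
  cat("<gng_ibic> ", spec_string(x$spec), ": iBIC = ", round(x$value, 2),
      " (log marginal ", round(x$log_marginal, 2), ", |M| = ", x$n_params,
      ", n = ", x$n_obs, ", k = ", x$k_samples, ")\n", sep = "")
  invisible(x)
}

# Single-move refinements of a spec: add bias, add the Pavlovian factor,
# refine the learning-rate split one level, refine the rho split.
refinements <- function(spec) {
  out <- list()
  if (spec$lr_split == "single") {
    out <- c(out, list(modify_spec(spec, lr_split = "pe_sign")))
  } else if (spec$lr_split == "pe_sign") {
    out <- c(out, list(modify_spec(spec, lr_split = "pe_sign_domain")))
  }
  if (spec$rho_split == "single") {
    out <- c(out, list(modify_spec(spec, rho_split = "domain")))
  }
  if (!spec$has_bias) out <- c(out, list(modify_spec(spec, bias = TRUE)))
  if (!spec$has_pavlovian) out <- c(out, list(modify_spec(spec, pavlovian = TRUE)))
  out
}

modify_spec <- function(spec, lr_split = spec$lr_split,
                        rho_split = spec$rho_split, bias = spec$has_bias,
                        pavlovian = spec$has_pavlovian) {
  gng_spec(lr_split = lr_split, rho_split = rho_split, bias = bias,
           pavlovian = pavlovian)
}

#' Stepwise forward model selection by iBIC
#'
#' Starts from the base model (one learning rate eps and one outcome
#' impact rho), and at each step enumerates the single-move extensions of
#' the incumbent — add the action bias, add the Pavlovian factor, refine
#' the learning-rate split one level (single -> by PE sign -> by PE sign
#' and domain), refine the rho split by domain — fits each candidate
#' hierarchically, scores it by [ibic()] with one shared Monte-Carlo seed
#' for the whole run, and accepts the candidate that decreases the iBIC
#' the most. The search stops when no candidate decreases the iBIC;
#' ties within 1e-6 are broken toward the smaller model (the incumbent).
#'
#' @param trials A multi-subject trial tibble.
#' @param seed Integer seed (restart draws and the shared iBIC stream are
#'   derived from it deterministically).
#' @param config A `gng_fit_config`; `k_samples` and `penalty_per_param`
#'   control the scoring.
#' @param start_spec Incumbent to start from (default: the base model).
#' @return An object of class `gng_selection`: a `steps` tibble (one row
#'   per candidate evaluated, with `step`, `spec`, `n_params`, `ibic`,
#'   `accepted`), the `winner` spec, and the winner's `gng_fit`.
#' @export
stepwise_select <- function(trials, seed = 1, config = gng_fit_config(),
                            start_spec = gng_spec()) {
  stopifnot(inherits(start_spec, "gng_spec"))
  ibic_seed <- seed + 10000L   # one shared Monte-Carlo stream per run

  score_spec <- function(spec) {
    fit <- em_fit(trials, spec, config = config, seed = seed)
    sc <- ibic(trials, fit, k_samples = config$k_samples, seed = ibic_seed,
               penalty_per_param = config$penalty_per_param)
    list(fit = fit, score = sc)
  }

  incumbent_spec <- start_spec
  incumbent <- tryCatch(score_spec(incumbent_spec), error = function(e) {
    abort(paste0("Fitting failed for candidate ", spec_string(incumbent_spec),
                 ": ", conditionMessage(e)))
  })
  rows <- list(tibble::tibble(
    step = 0L, spec = spec_string(incumbent_spec),
    n_params = n_params(incumbent_spec),
    ibic = incumbent$score$value,
    log_marginal = incumbent$score$log_marginal, accepted = TRUE))

  step <- 0L
  repeat {
    step <- step + 1L
    cands <- refinements(incumbent_spec)
    if (length(cands) == 0) break
    scored <- lapply(cands, function(sp) {
      tryCatch(score_spec(sp), error = function(e) {
        abort(paste0("Fitting failed for candidate ", spec_string(sp), ": ",
                     conditionMessage(e)))
      })
    })
    vals <- vapply(scored, function(s) s$score$value, numeric(1))
    best <- which.min(vals)
    improves <- vals[best] < incumbent$score$value - 1e-6
    rows <- c(rows, list(tibble::tibble(
      step = step,
      spec = vapply(cands, spec_string, ""),
      n_params = vapply(cands, n_params, 1L),
      ibic = vals,
      log_marginal = vapply(scored, function(s) s$score$log_marginal,
                            numeric(1)),
      accepted = improves & seq_along(cands) == best)))
    if (!improves) break
    incumbent_spec <- cands[[best]]
    incumbent <- scored[[best]]
  }

  structure(
    list(steps = dplyr::bind_rows(rows), winner = incumbent_spec,
         winner_fit = incumbent$fit, winner_ibic = incumbent$score,
         seed = seed, config = config),
    class = "gng_selection"
  )
}

#' @export
print.gng_selection <- function(x, ...) {
  cat("<gng_selection> winner: ", spec_string(x$winner), " (iBIC ",
      round(x$winner_ibic$value, 2), ")\n", sep = "")
  print(x$steps, n = Inf)
  invisible(x)
}

#' Tidiers for selection traces
#'
#' `tidy()` returns the full candidate table (one row per candidate and
#' step); `glance()` a one-row summary of the winning model.
#'
#' @param x A `gng_selection`.
#' @param ... Unused.
#' @export
tidy.gng_selection <- function(x, ...) x$steps

#' @rdname tidy.gng_selection
#' @export
glance.gng_selection <- function(x, ...) {
  tibble::tibble(
    winner = spec_string(x$winner),
    n_params = n_params(x$winner),
    ibic = x$winner_ibic$value,
    n_steps = max(x$steps$step),
    n_candidates = nrow(x$steps)
  )
}
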