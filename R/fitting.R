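#' Parameter transforms between natural and unconstrained scales
#'
#' Hierarchical fitting places normal population distributions on an
#' unconstrained ("transformed") scale: learning rates map through the
#' logit, outcome impacts rho through the log, and the action bias and
#' Pavlovian factor are already unconstrained (identity; the Pavlovian
#' factor is deliberately not sign-constrained). Round-trips are identity
#' to numerical precision.
#'
#' @param params A `gng_params` (natural scale) or, for the vector form,
#'   a named numeric vector whose names follow [param_names()].
#' @param direction `"to_unconstrained"` or `"to_natural"`.
#' @return `transform_params()` returns a named numeric vector on the
#'   requested scale (for a `gng_params` input, the free vector).
#' @export
#' @examples
#' transform_params(c(eps = 0.5, rho = 1), "to_unconstrained")  # 0, 0
transform_params <- function(params,
                             direction = c("to_unconstrained", "to_natural")) {
  direction <- match.arg(direction)
  free <- if (inherits(params, "gng_params")) params$free else params
  if (is.null(names(free))) abort("Parameter vector must be named.")
  if (direction == "to_unconstrained") to_unconstrained(free)
  else to_natural(free)
}

to_unconstrained <- function(free) {
  out <- free
  eps <- grep("^eps", names(free))
  rho <- grep("^rho", names(free))
  if (any(free[eps] <= 0 | free[eps] >= 1)) {
    abort("Learning rates must lie strictly in (0, 1) to transform.")
  }
  if (any(free[rho] <= 0)) abort("rho must be strictly positive to transform.")
  out[eps] <- stats::qlogis(free[eps])
  out[rho] <- log(free[rho])
  out
}

to_natural <- function(theta) {
  out <- theta
  eps <- grep("^eps", names(theta))
  rho <- grep("^rho", names(theta))
  out[eps] <- stats::plogis(theta[eps])
  out[rho] <- exp(theta[rho])
  out
}

#' Population prior (empirical-Bayes hyperparameters)
#'
#' Independent normal distributions per parameter on the transformed
#' scale. The default is weakly informative: mean 0 (i.e. eps = 0.5,
#' rho = 1, bias = pav = 0 on the natural scale) with variance 2.25
#' (SD 1.5), wide enough to cover the plausible natural-scale ranges.
#'
#' @param spec A `gng_spec`.
#' @param mu,sigma2 Optional named numeric vectors on the transformed
#'   scale (defaults: 0 and 2.25 for every parameter).
#' @return An object of class `gng_prior`.
#' @export
population_prior <- function(spec, mu = NULL, sigma2 = NULL) {
  nm <- param_names(spec)
  if (is.null(mu)) mu <- setNames(rep(0, length(nm)), nm)
  if (is.null(sigma2)) sigma2 <- setNames(rep(2.25, length(nm)), nm)
  if (!setequal(names(mu), nm) || !setequal(names(sigma2), nm)) {
    abort("Prior mu/sigma2 names must match param_names(spec).")
  }
  if (any(sigma2 <= 0)) abort("Prior variances must be positive.")
  structure(list(spec = spec, mu = mu[nm], sigma2 = sigma2[nm]),
            class = "gng_prior")
}

#' Fitting configuration
#'
#' @param n_restarts Optimizer restarts for the first-pass MAP estimates;
#'   initial points are drawn from the current prior, plus the prior mean.
#' @param warm_restarts Restarts in later EM iterations (warm-started from
#'   the previous MAP, plus the prior mean).
#' @param em_tol Convergence tolerance on the hyperparameters (max
#'   absolute change of any prior mean or variance).
#' @param em_max_iter Iteration cap for EM.
#' @param var_floor Floor on the population variances in the M-step,
#'   preventing prior collapse on degenerate cohorts.
#' @param hess_step Central-difference step for the numerical Hessian on
#'   the transformed scale.
#' @param hess_floor Floor on Hessian diagonal entries before inversion.
#' @param k_samples Monte-Carlo draws for the integrated BIC.
#' @param penalty_per_param Population-level free parameters counted per
#'   model parameter in the iBIC penalty: 2 (mean and variance, the
#'   default) or 1.
#' @param optim_maxit,optim_reltol Passed to [stats::optim()] (BFGS).
#' @return A list of class `gng_config`.
#' @export
gng_fit_config <- function(n_restarts = 10, warm_restarts = 2,
                           em_tol = 1e-3, em_max_iter = 200,
                           var_floor = 1e-6, hess_step = 1e-4,
                           hess_floor = 1e-6, k_samples = 1000,
                           penalty_per_param = 2,
                           optim_maxit = 500, optim_reltol = 1e-10) {
  stopifnot(n_restarts >= 1, warm_restarts >= 1, em_max_iter >= 1,
            penalty_per_param %in% c(1, 2))
  structure(
    list(n_restarts = n_restarts, warm_restarts = warm_restarts,
         em_tol = em_tol, em_max_iter = em_max_iter, var_floor = var_floor,
         hess_step = hess_step, hess_floor = hess_floor,
         k_samples = k_samples, penalty_per_param = penalty_per_param,
         optim_maxit = optim_maxit, optim_reltol = optim_reltol),
    class = "gng_config"
  )
}

spec_codes <- function(spec) {
  list(lr = n_eps(spec), rho = n_rho(spec),
       b = as.integer(spec$has_bias), p = as.integer(spec$has_pavlovian))
}

# MAP estimation for one encoded session; starts is a list of transformed
# start vectors. Returns the best converged optim result + Laplace terms.
fit_session <- function(sess, spec, mu, sigma2, starts, config) {
  cd <- spec_codes(spec)
  fn <- function(theta) {
    cpp_neg_logpost(theta, sess$cond, sess$act, sess$out,
                    cd$lr, cd$rho, cd$b, cd$p, mu, sigma2)
  }
  gr <- function(theta) {
    cpp_neg_logpost_grad(theta, sess$cond, sess$act, sess$out,
                         cd$lr, cd$rho, cd$b, cd$p, mu, sigma2)
  }
  best <- NULL
  fails <- character(0)
  for (st in starts) {
    res <- tryCatch(
      optim(st, fn, gr, method = "BFGS",
            control = list(maxit = config$optim_maxit,
                           reltol = config$optim_reltol)),
      error = function(e) e
    )
    if (inherits(res, "error")) { fails <- c(fails, conditionMessage(res)); next }
    if (!is.finite(res$value)) { fails <- c(fails, "non-finite objective"); next }
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    abort(paste0("All optimizer restarts failed: ",
                 paste(unique(fails), collapse = "; ")))
  }
  theta <- best$par
  H <- num_hessian(fn, theta, config$hess_step)
  hess <- pmax(diag(H), config$hess_floor)
  # Laplace (co)variance: diagonal of the inverse full Hessian, so that
  # each parameter's marginal posterior width survives correlations with
  # the others; fall back to the diagonal curvature if H is not usable.
  lap_var <- tryCatch({
    v <- diag(chol2inv(chol(H)))
    if (any(!is.finite(v) | v <= 0)) stop("bad inverse")
    v
  }, error = function(e) 1 / hess)
  p8 <- cpp_expand_theta(theta, cd$lr, cd$rho, cd$b, cd$p)
  ll <- cpp_session_loglik(sess$cond, sess$act, sess$out, p8, cd$p == 1L)
  list(theta = theta, hessian = hess, lap_var = lap_var,
       log_posterior = -best$value, loglik = ll,
       convergence = best$convergence)
}

# Full numerical Hessian by central differences (step h per coordinate).
num_hessian <- function(fn, theta, h) {
  k <- length(theta)
  f0 <- fn(theta)
  H <- matrix(0, k, k)
  fp <- fm <- numeric(k)
  for (i in seq_len(k)) {
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    fp[i] <- fn(tp); fm[i] <- fn(tm)
    H[i, i] <- (fp[i] - 2 * f0 + fm[i]) / h^2
  }
  if (k > 1) {
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      tpp <- theta; tpp[i] <- tpp[i] + h; tpp[j] <- tpp[j] + h
      tmm <- theta; tmm[i] <- tmm[i] - h; tmm[j] <- tmm[j] - h
      H[i, j] <- H[j, i] <-
        (fn(tpp) - fp[i] - fp[j] + 2 * f0 - fm[i] - fm[j] + fn(tmm)) /
        (2 * h^2)
    }
  }
  H
}

make_starts <- function(mu, sigma2, n_random, warm = NULL) {
  starts <- list()
  if (!is.null(warm)) starts <- c(starts, list(warm))
  starts <- c(starts, list(mu))
  if (n_random > 0) {
    draws <- replicate(n_random, rnorm(length(mu), mu, sqrt(sigma2)),
                       simplify = FALSE)
    starts <- c(starts, draws)
  }
  starts
}

#' Per-subject MAP estimate under a population prior
#'
#' Maximizes log p(choices | theta) + log N(theta | mu, sigma2) on the
#' transformed scale by multi-start BFGS (initial points drawn from the
#' prior, plus the prior mean) and measures the curvature of the negative
#' log posterior at the optimum by central finite differences (the Laplace
#' approximation; the per-parameter variance is the inverse curvature).
#'
#' @param trials A single subject's trial tibble.
#' @param spec A `gng_spec`.
#' @param prior A `gng_prior` (default: the weakly informative default).
#' @param n_restarts Number of random restarts (in addition to the prior
#'   mean).
#' @param seed Optional integer seed for the restart draws.
#' @param config A `gng_fit_config` for optimizer/Hessian settings.
#' @return A list of class `gng_map` with elements `par` (natural-scale
#'   MAP), `theta` (transformed scale), `hessian` (per-parameter
#'   curvature), `lap_var`, `log_posterior`, `loglik` and `convergence`.
#' @export
map_estimate <- function(trials, spec, prior = population_prior(spec),
                         n_restarts = 10, seed = NULL,
                         config = gng_fit_config()) {
  stopifnot(inherits(spec, "gng_spec"), inherits(prior, "gng_prior"))
  if (!identical(spec_string(prior$spec), spec_string(spec))) {
    abort("Prior was built for a different model spec.")
  }
  sess <- split_sessions(trials)
  if (length(sess) != 1) abort("`map_estimate()` expects a single subject.")
  sess <- sess[[1]]
  mu <- unname(prior$mu); sigma2 <- unname(prior$sigma2)
  starts <- with_seed(seed, make_starts(mu, sigma2, n_restarts - 1))
  res <- fit_session(sess, spec, mu, sigma2, starts, config)
  nm <- param_names(spec)
  theta <- setNames(res$theta, nm)
  structure(
    c(list(spec = spec, par = to_natural(theta), theta = theta),
      res[c("hessian", "lap_var", "log_posterior", "loglik", "convergence")]),
    class = "gng_map"
  )
}

#' Hierarchical type-II maximum-likelihood fit (EM with Laplace)
#'
#' Alternates an E-step — per-subject MAP estimates and Laplace curvatures
#' under the current population prior — with an M-step that re-estimates
#' the prior: each parameter's population mean becomes the mean of the
#' subject MAPs and its variance the mean squared deviation plus the mean
#' Laplace variance (floored at `var_floor`). Iterates until the largest
#' absolute change in any hyperparameter falls below `em_tol` or the
#' iteration cap is reached. Subjects with degenerate behaviour (all-go or
#' all-nogo sessions) are fitted normally — the prior regularizes — with a
#' warning.
#'
#' @param trials A multi-subject trial tibble (column `subject` present).
#' @param spec A `gng_spec`.
#' @param config A `gng_fit_config`.
#' @param seed Integer seed governing restart draws.
#' @return An object of class `gng_fit`: the fitted prior, a per-subject
#'   parameter table (natural scale), Laplace variances, the EM trace
#'   (hyperparameters and approximate evidence per iteration) and
#'   bookkeeping (`converged`, `iterations`, `n_obs`).
#' @export
em_fit <- function(trials, spec = gng_spec(), config = gng_fit_config(),
                   seed = 1) {
  stopifnot(inherits(spec, "gng_spec"), inherits(config, "gng_config"))
  old_rng <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_rng)) assign(".Random.seed", old_rng, envir = globalenv())
  })
  sessions <- split_sessions(trials)
  if (length(sessions) < 2) abort("em_fit() needs a cohort of >= 2 subjects.")
  nm <- param_names(spec)
  k <- length(nm)
  n_sub <- length(sessions)

  degenerate <- vapply(sessions, function(s) length(unique(s$act)) == 1L,
                       logical(1))
  if (any(degenerate)) {
    warn(paste0("Degenerate session(s) (always go or never go): ",
                paste(names(sessions)[degenerate], collapse = ", "),
                "; the population prior regularizes their estimates."))
  }

  mu <- rep(0, k)
  sigma2 <- rep(2.25, k)
  theta_mat <- matrix(NA_real_, nrow = n_sub, ncol = k)
  lap_mat <- matrix(NA_real_, nrow = n_sub, ncol = k)
  lp <- ll <- numeric(n_sub)
  trace <- vector("list", config$em_max_iter)
  converged <- FALSE
  iter_done <- 0

  for (iter in seq_len(config$em_max_iter)) {
    set.seed(seed + iter)
    for (j in seq_len(n_sub)) {
      starts <- if (iter == 1) {
        make_starts(mu, sigma2, config$n_restarts - 1)
      } else if (config$warm_restarts == 1) {
        list(theta_mat[j, ])
      } else {
        make_starts(mu, sigma2, config$warm_restarts - 2,
                    warm = theta_mat[j, ])
      }
      res <- tryCatch(
        fit_session(sessions[[j]], spec, mu, sigma2, starts, config),
        error = function(e) {
          abort(paste0("Fitting failed for subject ", names(sessions)[j],
                       ": ", conditionMessage(e)))
        })
      theta_mat[j, ] <- res$theta
      lap_mat[j, ] <- res$lap_var
      lp[j] <- res$log_posterior
      ll[j] <- res$loglik
    }
    # Laplace approximation to the log evidence at the current prior
    evidence <- sum(lp) + 0.5 * sum(log(2 * pi * lap_mat))
    mu_new <- colMeans(theta_mat)
    sigma2_new <- pmax(colMeans(sweep(theta_mat, 2, mu_new)^2 + lap_mat),
                       config$var_floor)
    delta <- max(abs(mu_new - mu), abs(sigma2_new - sigma2))
    trace[[iter]] <- tibble::tibble(
      iteration = iter, evidence = evidence, max_change = delta,
      hyper = list(tibble::tibble(parameter = nm, mu = mu_new,
                                  sigma2 = sigma2_new)))
    mu <- mu_new; sigma2 <- sigma2_new
    iter_done <- iter
    if (delta < config$em_tol) { converged <- TRUE; break }
  }

  theta_named <- theta_mat
  colnames(theta_named) <- colnames(lap_mat) <- nm
  nat <- t(apply(theta_named, 1, function(row) to_natural(setNames(row, nm))))
  subjects <- tibble::as_tibble(nat)
  subjects <- tibble::add_column(subjects, subject = names(sessions),
                                 .before = 1)
  subjects$loglik <- ll
  subjects$log_posterior <- lp

  structure(
    list(spec = spec,
         prior = population_prior(spec, mu = setNames(mu, nm),
                                  sigma2 = setNames(sigma2, nm)),
         subjects = subjects,
         theta = theta_named,
         laplace_var = lap_mat,
         trace = dplyr::bind_rows(trace[seq_len(iter_done)]),
         converged = converged,
         iterations = iter_done,
         n_obs = sum(vapply(sessions, function(s) length(s$cond), 1L)),
         config = config,
         seed = seed),
    class = "gng_fit"
  )
}

#' Population means of a hierarchical fit on the natural scale
#'
#' @param fit A `gng_fit`.
#' @return A named numeric vector: the fitted population means mapped
#'   back to the natural scale (inverse-logit for learning rates, exp for
#'   rho).
#' @export
population_means <- function(fit) {
  stopifnot(inherits(fit, "gng_fit"))
  to_natural(fit$prior$mu)
}

#' @export
print.gng_fit <- function(x, ...) {
  cat("<gng_fit> ", spec_string(x$spec), ": ", nrow(x$subjects),
      " subjects, ", x$n_obs, " choices\n", sep = "")
  cat("EM ", x$iterations, " iterations (",
      if (x$converged) "converged" else "iteration cap reached", ")\n",
      sep = "")
  cat("Population means (natural scale):\n")
  print(round(population_means(x), 4))
  invisible(x)
}

#' Tidiers for hierarchical fits
#'
#' `tidy()` returns one row per subject and parameter (natural scale,
#' with the transformed-scale estimate and its Laplace standard error);
#' `glance()` a one-row model summary.
#'
#' @param x A `gng_fit`.
#' @param ... Unused.
#' @export
tidy.gng_fit <- function(x, ...) {
  nm <- param_names(x$spec)
  long <- tidyr::pivot_longer(x$subjects[, c("subject", nm)],
                              cols = tidyr::all_of(nm),
                              names_to = "parameter", values_to = "estimate")
  theta <- tidyr::pivot_longer(
    tibble::as_tibble(cbind(subject = x$subjects$subject,
                            as.data.frame(x$theta))),
    cols = tidyr::all_of(nm), names_to = "parameter",
    values_to = "transformed")
  se <- tidyr::pivot_longer(
    tibble::as_tibble(cbind(subject = x$subjects$subject,
                            as.data.frame(sqrt(x$laplace_var)))),
    cols = tidyr::all_of(nm), names_to = "parameter",
    values_to = "std_error_transformed")
  out <- dplyr::left_join(long, theta, by = c("subject", "parameter"))
  out <- dplyr::left_join(out, se, by = c("subject", "parameter"))
  out$transformed <- as.numeric(out$transformed)
  out$std_error_transformed <- as.numeric(out$std_error_transformed)
  out
}

#' @rdname tidy.gng_fit
#' @export
glance.gng_fit <- function(x, ...) {
  tibble::tibble(
    spec = spec_string(x$spec),
    n_subjects = nrow(x$subjects),
    n_obs = x$n_obs,
    n_params = n_params(x$spec),
    loglik = sum(x$subjects$loglik),
    iterations = x$iterations,
    converged = x$converged
  )
}
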