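test_that("transforms map to the unconstrained scale and round-trip", {
  expect_equal(unname(transform_params(c(eps = 0.5), "to_unconstrained")), 0)
  expect_equal(unname(transform_params(c(rho = 1), "to_unconstrained")), 0)
  nat <- c(eps = 0.33, rho = 2.4, bias = -0.7, pav = 1.2)
  back <- transform_params(transform_params(nat, "to_unconstrained"),
                           "to_natural")
  expect_equal(back, nat, tolerance = 1e-10)
  # gng_params round-trip across the lattice
  for (i in seq_along(all_specs())) {
    par <- random_params(all_specs()[[i]], seed = 300 + i)
    theta <- transform_params(par, "to_unconstrained")
    expect_equal(transform_params(theta, "to_natural"), par$free,
                 tolerance = 1e-10)
  }
  expect_error(transform_params(c(eps = 1.2), "to_unconstrained"), "\\(0, 1\\)")
  expect_error(transform_params(c(rho = -1), "to_unconstrained"), "positive")
})

test_that("an infinitely strong prior pins the MAP at the prior mean", {
  sp <- gng_spec()
  s <- random_session(10, seed = 1)
  mu <- c(eps = stats::qlogis(0.37), rho = log(1.6))
  prior <- population_prior(sp, mu = mu,
                            sigma2 = c(eps = 1e-10, rho = 1e-10))
  m <- map_estimate(s, sp, prior, n_restarts = 2, seed = 2)
  expect_equal(unname(m$theta), unname(mu), tolerance = 1e-4)
  expect_equal(m$par[["eps"]], 0.37, tolerance = 1e-4)
})

test_that("multi-start MAP estimation is restart-robust", {
  sp <- gng_spec(bias = TRUE)
  p <- gng_params(sp, eps = 0.4, rho = 2, bias = 0.3)
  s <- simulate_agent(generate_schedule(60, seed = 3), p, seed = 4)
  m1 <- map_estimate(s, sp, n_restarts = 6, seed = 10)
  m2 <- map_estimate(s, sp, n_restarts = 6, seed = 99)
  expect_equal(m1$theta, m2$theta, tolerance = 1e-6)
  expect_true(all(m1$hessian > 0))
  expect_true(all(m1$lap_var > 0))
})

test_that("MAP recovers a known learning rate from single sessions", {
  sp <- gng_spec()
  p <- gng_params(sp, eps = 0.5, rho = 2)
  errs <- vapply(1:50, function(i) {
    s <- simulate_agent(generate_schedule(60, seed = 400 + i), p,
                        seed = 900 + i)
    m <- map_estimate(s, sp, n_restarts = 4, seed = i)
    m$par[["eps"]] - 0.5
  }, numeric(1))
  expect_lt(abs(median(errs)), 0.15)
})

test_that("the prior washes out with enough data (ML consistency)", {
  sp <- gng_spec()
  p <- gng_params(sp, eps = 0.3, rho = 2)
  s <- simulate_agent(generate_schedule(2500, seed = 5), p, seed = 6)
  m <- map_estimate(s, sp, n_restarts = 4, seed = 7)
  # unpenalized ML oracle: optimize the bare likelihood from the truth
  nll <- function(theta) {
    -session_loglik(s, gng_params(sp, transform_params(
      stats::setNames(theta, c("eps", "rho")), "to_natural")))
  }
  ml <- optim(c(stats::qlogis(0.3), log(2)), nll, method = "BFGS")
  expect_equal(unname(m$theta), ml$par, tolerance = 1e-2)
})

test_that("EM hyperparameter updates equal the moment equations (M-step)", {
  coh <- random_cohort(4, n_per_condition = 5, seed = 60)
  cfg <- gng_fit_config(n_restarts = 3, em_max_iter = 1)
  fit <- em_fit(coh, gng_spec(), config = cfg, seed = 5)
  mu_hand <- colMeans(fit$theta)
  dev2 <- sweep(fit$theta, 2, mu_hand)^2
  sigma2_hand <- pmax(colMeans(dev2 + fit$laplace_var), cfg$var_floor)
  expect_equal(unname(fit$prior$mu), unname(mu_hand), tolerance = 1e-12)
  expect_equal(unname(fit$prior$sigma2), unname(sigma2_hand),
               tolerance = 1e-12)
})

test_that("at convergence the E-step is self-consistent", {
  sp <- gng_spec()
  g <- group_spec("a", 8, sp, means = c(eps = 0.3, rho = 2), sds = 0.3)
  coh <- generate_cohort(list(g), n_per_condition = 30, seed = 8)
  fit <- em_fit(coh$trials, sp, config = gng_fit_config(n_restarts = 4),
                seed = 2)
  expect_true(fit$converged)
  # re-fitting each subject at the returned prior moves no MAP materially
  for (id in fit$subjects$subject[c(1, 4, 8)]) {
    s <- coh$trials[coh$trials$subject == id, ]
    m <- map_estimate(s, sp, fit$prior, n_restarts = 4, seed = 3)
    expect_equal(unname(m$theta),
                 unname(fit$theta[fit$subjects$subject == id, ]),
                 tolerance = 1e-3)
  }
  # Laplace variances positive for every subject in the accepted fit
  expect_true(all(fit$laplace_var > 0))
  # approximate evidence does not decrease (up to numerical tolerance)
  expect_true(all(diff(fit$trace$evidence) > -0.5))
})

test_that("EM recovers a population mean over a simulated cohort", {
  sp <- gng_spec()
  g <- group_spec("a", 40, sp, means = c(eps = 0.35, rho = 2), sds = 0.5)
  coh <- generate_cohort(list(g), n_per_condition = 60, seed = 13)
  fit <- em_fit(coh$trials, sp, config = gng_fit_config(n_restarts = 4),
                seed = 3)
  expect_lt(abs(population_means(fit)[["eps"]] - 0.35), 0.07)
})

test_that("identical sessions shrink the population variance", {
  s <- random_session(8, seed = 70, subject = "s1")
  coh <- dplyr::bind_rows(lapply(1:5, function(i) {
    s$subject <- sprintf("s%02d", i); s
  }))
  cfg <- gng_fit_config(n_restarts = 3, em_max_iter = 25)
  fit <- em_fit(coh, gng_spec(), config = cfg, seed = 4)
  # no between-subject variance: sigma2 falls from its initial value and
  # keeps decreasing toward the floor across iterations
  sig_trace <- t(vapply(fit$trace$hyper, function(h) h$sigma2, numeric(2)))
  expect_true(all(fit$prior$sigma2 < 2.25))
  expect_true(all(sig_trace[nrow(sig_trace), ] <= sig_trace[1, ] + 1e-8))
})

test_that("degenerate all-go subjects are fitted with a warning", {
  sched <- generate_schedule(5, seed = 80)
  allgo <- dplyr::bind_rows(lapply(1:3, function(i) tibble::tibble(
    subject = paste0("g", i), trial = sched$trial,
    condition = sched$condition, action = "go",
    outcome = sample_outcomes(sched$condition, "go", seed = 80 + i))))
  cfg <- gng_fit_config(n_restarts = 2, em_max_iter = 5)
  expect_warning(fit <- em_fit(allgo, gng_spec(bias = TRUE), config = cfg,
                               seed = 6), "Degenerate")
  expect_true(all(is.finite(fit$theta)))
})

test_that("cohorts below two subjects are rejected", {
  expect_error(em_fit(random_session(5, seed = 90), gng_spec()),
               ">= 2 subjects")
})

test_that("tidy and glance summarise fits in broom style", {
  coh <- random_cohort(3, n_per_condition = 5, seed = 95)
  fit <- em_fit(coh, gng_spec(), config = gng_fit_config(
    n_restarts = 2, em_max_iter = 3), seed = 7)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 3 * 2)
  expect_named(td, c("subject", "parameter", "estimate", "transformed",
                     "std_error_transformed"))
  expect_equal(sort(unique(td$parameter)), c("eps", "rho"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_subjects, 3)
  expect_equal(gl$n_obs, 60)
})
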