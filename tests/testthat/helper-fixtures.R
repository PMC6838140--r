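# Shared fixtures, all generated in code at test time.

winning_means <- function() {
  c(eps_GP = 0.170, eps_GN = 0.160, eps_LP = 0.330, eps_LN = 0.160,
    rho = 2.0, bias = 0.3, pav = 0.4)
}

winning_params <- function(...) {
  m <- winning_means()
  over <- c(...)
  m[names(over)] <- over
  gng_params(winning_spec(), m)
}

# A session with random 50/50 actions and contingency-sampled outcomes —
# exercises every branch of the likelihood without favouring any model.
random_session <- function(n_per_condition = 5, seed = 1, subject = "s1") {
  sched <- generate_schedule(n_per_condition, seed = seed)
  withr_seed <- seed + 5000
  set.seed(withr_seed)
  action <- sample(c("go", "nogo"), nrow(sched), replace = TRUE)
  outcome <- sample_outcomes(sched$condition, action)
  tibble::tibble(subject = subject, trial = sched$trial,
                 condition = sched$condition, action = action,
                 outcome = outcome)
}

random_cohort <- function(n_subjects, n_per_condition = 5, seed = 1) {
  dplyr::bind_rows(lapply(seq_len(n_subjects), function(i) {
    random_session(n_per_condition, seed = seed + i,
                   subject = sprintf("s%02d", i))
  }))
}

# A spec + natural-scale parameter draw for every model in the lattice
# reachable by the stepwise moves.
all_specs <- function() {
  list(
    gng_spec(),
    gng_spec(bias = TRUE),
    gng_spec(pavlovian = TRUE),
    gng_spec("pe_sign"),
    gng_spec(rho_split = "domain"),
    gng_spec("pe_sign", bias = TRUE, pavlovian = TRUE),
    gng_spec("pe_sign_domain", rho_split = "domain"),
    winning_spec(),
    gng_spec("pe_sign_domain", rho_split = "domain", bias = TRUE,
             pavlovian = TRUE)
  )
}

random_params <- function(spec, seed) {
  set.seed(seed)
  nm <- param_names(spec)
  vals <- vapply(nm, function(p) {
    if (grepl("^eps", p)) runif(1, 0.05, 0.9)
    else if (grepl("^rho", p)) runif(1, 0.5, 3)
    else rnorm(1, 0, 0.7)
  }, numeric(1))
  gng_params(spec, vals)
}
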