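# Independent naive re-implementations used as oracles. These deliberately
# share no code with the package internals: plain data-frame loops, named
# lookups, unstabilized softmax.

oracle_cond_info <- function(condition) {
  info <- list(
    go_gain    = list(s = 1, domain = "gain", correct = "go"),
    nogo_gain  = list(s = 2, domain = "gain", correct = "nogo"),
    go_avoid   = list(s = 3, domain = "loss", correct = "go"),
    nogo_avoid = list(s = 4, domain = "loss", correct = "nogo")
  )
  info[[condition]]
}

# Per-trial loop over a session: softmax of raw exponentials, delta-rule
# updates of the chosen action's Q, stimulus-value update when has_pav.
oracle_loglik <- function(trials, p8, has_pav) {
  Q <- matrix(0, nrow = 4, ncol = 2, dimnames = list(NULL, c("nogo", "go")))
  V <- rep(0, 4)
  ll <- 0
  for (i in seq_len(nrow(trials))) {
    ci <- oracle_cond_info(trials$condition[i])
    s <- ci$s
    w_go <- Q[s, "go"] + p8[["bias"]] +
      (if (has_pav) p8[["pav"]] * V[s] else 0)
    w_nogo <- Q[s, "nogo"]
    p_go <- exp(w_go) / (exp(w_go) + exp(w_nogo))
    ll <- ll + log(if (trials$action[i] == "go") p_go else 1 - p_go)
    rho <- if (ci$domain == "gain") p8[["rho_G"]] else p8[["rho_L"]]
    a <- trials$action[i]
    delta <- rho * trials$outcome[i] - Q[s, a]
    eps <- p8[[paste0("eps_", if (ci$domain == "gain") "G" else "L",
                      if (delta >= 0) "P" else "N")]]
    Q[s, a] <- Q[s, a] + eps * delta
    if (has_pav) {
      dv <- rho * trials$outcome[i] - V[s]
      epsv <- p8[[paste0("eps_", if (ci$domain == "gain") "G" else "L",
                         if (dv >= 0) "P" else "N")]]
      V[s] <- V[s] + epsv * dv
    }
  }
  as.numeric(ll)
}

# Expand a named transformed-scale draw to the 8-slot natural block by
# explicit case analysis (independent of the package's expansion).
oracle_expand <- function(theta, spec_str) {
  f <- strsplit(spec_str, ",")[[1]]
  get_f <- function(key) {
    as.integer(sub(paste0(key, "="), "", f[grep(paste0("^", key, "="), f)]))
  }
  lr <- get_f("lr"); rho <- get_f("rho")
  has_b <- get_f("bias") == 1; has_p <- get_f("pav") == 1
  inv_logit <- function(x) 1 / (1 + exp(-x))
  i <- 1
  if (lr == 1) {
    e <- rep(inv_logit(theta[i]), 4); i <- i + 1
  } else if (lr == 2) {
    e <- c(inv_logit(theta[i]), inv_logit(theta[i + 1]),
           inv_logit(theta[i]), inv_logit(theta[i + 1])); i <- i + 2
  } else {
    e <- inv_logit(theta[i:(i + 3)]); i <- i + 4
  }
  if (rho == 1) {
    r <- rep(exp(theta[i]), 2); i <- i + 1
  } else {
    r <- exp(theta[i:(i + 1)]); i <- i + 2
  }
  b <- if (has_b) { v <- theta[i]; i <- i + 1; v } else 0
  p <- if (has_p) theta[i] else 0
  stats::setNames(c(e, r, b, p),
                  c("eps_GP", "eps_GN", "eps_LP", "eps_LN",
                    "rho_G", "rho_L", "bias", "pav"))
}

# Brute-force integrated BIC: same draw stream as the package (single
# rnorm call under the seed), naive loops for everything else.
oracle_ibic <- function(trials, mu, sigma2, spec_str, k, seed,
                        penalty_per_param = 2) {
  np <- length(mu)
  set.seed(seed)
  draws <- matrix(rnorm(k * np, mean = rep(mu, each = k),
                        sd = rep(sqrt(sigma2), each = k)),
                  nrow = k, ncol = np)
  has_p <- grepl("pav=1", spec_str)
  subjects <- split(trials, trials$subject)
  log_marginal <- 0
  n_obs <- 0
  for (d in subjects) {
    d <- d[order(d$trial), ]
    lls <- numeric(k)
    for (j in seq_len(k)) {
      p8 <- oracle_expand(draws[j, ], spec_str)
      lls[j] <- oracle_loglik(d, as.list(p8), has_p)
    }
    m <- max(lls)
    log_marginal <- log_marginal + m + log(mean(exp(lls - m)))
    n_obs <- n_obs + nrow(d)
  }
  n_model_params <- np
  -2 * log_marginal + penalty_per_param * n_model_params * log(n_obs)
}
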