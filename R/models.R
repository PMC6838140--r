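#' Define a model in the nested delta-rule family
#'
#' Every model learns action values Q(a, s) by the delta rule
#' Q <- Q + eps * delta with prediction error delta = rho * r - Q, and
#' chooses by a softmax over action weights W. The family is spanned by
#' four structural choices:
#'
#' * `lr_split`: one learning rate (`"single"`), separate rates for
#'   positive vs. negative prediction errors (`"pe_sign"`), or four rates
#'   further split by gain/loss domain (`"pe_sign_domain"`:
#'   eps_GP, eps_GN, eps_LP, eps_LN).
#' * `rho_split`: one subjective outcome impact rho (`"single"`) or
#'   separate rho_G / rho_L by domain (`"domain"`).
#' * `bias`: an action bias b added to the go weight.
#' * `pavlovian`: a Pavlovian factor pi coupling the stimulus value V(s)
#'   into the go weight (W_go = Q_go + b + pi * V); V is updated by
#'   V <- V + eps * (rho * r - V) on every trial using the learning rate
#'   selected by the stimulus prediction-error sign and the trial domain.
#'
#' The base model (`gng_spec()`) has one eps and one rho; the fully split
#' model with bias and Pavlovian factor has 8 parameters, and the lattice
#' spans 12 distinct candidate parameters in total. rho doubles as the
#' value scale of the softmax, so there is no separate inverse temperature.
#'
#' @param lr_split Learning-rate structure, see above.
#' @param rho_split Outcome-impact structure.
#' @param bias Include the action bias b?
#' @param pavlovian Include the Pavlovian factor pi (and stimulus value V)?
#' @return An object of class `gng_spec`.
#' @export
#' @examples
#' gng_spec()                                   # base model: eps, rho
#' winning_spec()                               # 4 eps + rho + b + pi
#' n_params(winning_spec())
gng_spec <- function(lr_split = c("single", "pe_sign", "pe_sign_domain"),
                     rho_split = c("single", "domain"),
                     bias = FALSE, pavlovian = FALSE) {
  lr_split <- match.arg(lr_split)
  rho_split <- match.arg(rho_split)
  stopifnot(is.logical(bias), length(bias) == 1,
            is.logical(pavlovian), length(pavlovian) == 1)
  structure(
    list(lr_split = lr_split, rho_split = rho_split,
         has_bias = bias, has_pavlovian = pavlovian),
    class = "gng_spec"
  )
}

#' @rdname gng_spec
#' @export
winning_spec <- function() {
  gng_spec(lr_split = "pe_sign_domain", rho_split = "single",
           bias = TRUE, pavlovian = TRUE)
}

n_eps <- function(spec) {
  switch(spec$lr_split, single = 1L, pe_sign = 2L, pe_sign_domain = 4L)
}
n_rho <- function(spec) switch(spec$rho_split, single = 1L, domain = 2L)

#' @rdname gng_spec
#' @param spec A `gng_spec`.
#' @export
n_params <- function(spec) {
  n_eps(spec) + n_rho(spec) + spec$has_bias + spec$has_pavlovian
}

#' @rdname gng_spec
#' @export
param_names <- function(spec) {
  eps <- switch(spec$lr_split,
    single = "eps",
    pe_sign = c("eps_P", "eps_N"),
    pe_sign_domain = c("eps_GP", "eps_GN", "eps_LP", "eps_LN"))
  rho <- switch(spec$rho_split, single = "rho", domain = c("rho_G", "rho_L"))
  c(eps, rho, if (spec$has_bias) "bias", if (spec$has_pavlovian) "pav")
}

#' Compact model-spec strings
#'
#' Model specs serialize to `lr=<1|2|4>,rho=<1|2>,bias=<0|1>,pav=<0|1>`
#' (e.g. the winning model is `"lr=4,rho=1,bias=1,pav=1"`); the order of
#' the four fields is fixed and all four are required.
#'
#' @param spec A `gng_spec`.
#' @param x A spec string.
#' @return `spec_string()` a string; `parse_spec()` a `gng_spec`.
#' @export
#' @examples
#' spec_string(winning_spec())
#' parse_spec("lr=2,rho=1,bias=0,pav=1")
spec_string <- function(spec) {
  sprintf("lr=%d,rho=%d,bias=%d,pav=%d", n_eps(spec), n_rho(spec),
          as.integer(spec$has_bias), as.integer(spec$has_pavlovian))
}

#' @rdname spec_string
#' @export
parse_spec <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  parts <- strsplit(x, ",", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  bad <- parts[vapply(kv, length, 1L) != 2]
  if (length(bad) > 0) {
    abort(paste0("Malformed spec token(s): ", paste(bad, collapse = ", ")))
  }
  vals <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  extra <- setdiff(names(vals), c("lr", "rho", "bias", "pav"))
  if (length(extra) > 0 || !setequal(names(vals), c("lr", "rho", "bias", "pav"))) {
    abort(paste0("Spec string must have fields lr, rho, bias, pav; got: ", x))
  }
  lr <- match(vals[["lr"]], c("1", "2", "4"))
  rho <- match(vals[["rho"]], c("1", "2"))
  if (is.na(lr)) abort(paste0("Invalid token: lr=", vals[["lr"]]))
  if (is.na(rho)) abort(paste0("Invalid token: rho=", vals[["rho"]]))
  if (!vals[["bias"]] %in% c("0", "1")) {
    abort(paste0("Invalid token: bias=", vals[["bias"]]))
  }
  if (!vals[["pav"]] %in% c("0", "1")) {
    abort(paste0("Invalid token: pav=", vals[["pav"]]))
  }
  gng_spec(
    lr_split = c("single", "pe_sign", "pe_sign_domain")[lr],
    rho_split = c("single", "domain")[rho],
    bias = vals[["bias"]] == "1",
    pavlovian = vals[["pav"]] == "1"
  )
}

#' @export
print.gng_spec <- function(x, ...) {
  cat("<gng_spec> ", spec_string(x), " (", n_params(x), " parameters: ",
      paste(param_names(x), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Construct a subject-level parameter vector
#'
#' Parameters live on the natural scale: learning rates in (0, 1),
#' outcome impacts rho > 0, bias and Pavlovian factor unconstrained
#' reals. The values must be named after `param_names(spec)`.
#'
#' @param spec A `gng_spec`.
#' @param ... Named parameter values, or a single named numeric vector.
#' @return An object of class `gng_params` carrying the spec, the free
#'   parameter vector and the expanded 8-slot block
#'   (eps_GP, eps_GN, eps_LP, eps_LN, rho_G, rho_L, bias, pav).
#' @export
#' @examples
#' gng_params(gng_spec(), eps = 0.2, rho = 2)
gng_params <- function(spec, ...) {
  dots <- list(...)
  free <- if (length(dots) == 1 && is.null(names(dots)) ||
              (length(dots) == 1 && is.numeric(dots[[1]]) && length(dots[[1]]) > 1)) {
    dots[[1]]
  } else {
    unlist(dots)
  }
  nm <- param_names(spec)
  if (!setequal(names(free), nm)) {
    abort(paste0("Parameters must be named exactly: ",
                 paste(nm, collapse = ", ")))
  }
  free <- free[nm]
  eps <- free[grep("^eps", nm)]
  rho <- free[grep("^rho", nm)]
  if (any(eps <= 0 | eps >= 1)) abort("Learning rates must lie strictly in (0, 1).")
  if (any(rho <= 0)) abort("Outcome impacts rho must be strictly positive.")
  structure(
    list(spec = spec, free = free, p8 = expand_free(spec, free)),
    class = "gng_params"
  )
}

# Natural-scale free vector -> 8-slot full block
# (eps_GP, eps_GN, eps_LP, eps_LN, rho_G, rho_L, bias, pav).
expand_free <- function(spec, free) {
  eps <- switch(spec$lr_split,
    single = rep(free[["eps"]], 4),
    pe_sign = c(free[["eps_P"]], free[["eps_N"]],
                free[["eps_P"]], free[["eps_N"]]),
    pe_sign_domain = c(free[["eps_GP"]], free[["eps_GN"]],
                       free[["eps_LP"]], free[["eps_LN"]]))
  rho <- switch(spec$rho_split,
    single = rep(free[["rho"]], 2),
    domain = c(free[["rho_G"]], free[["rho_L"]]))
  p8 <- c(eps, rho,
          if (spec$has_bias) free[["bias"]] else 0,
          if (spec$has_pavlovian) free[["pav"]] else 0)
  names(p8) <- c("eps_GP", "eps_GN", "eps_LP", "eps_LN",
                 "rho_G", "rho_L", "bias", "pav")
  p8
}

#' @export
print.gng_params <- function(x, ...) {
  cat("<gng_params> ", spec_string(x$spec), "\n", sep = "")
  print(round(x$free, 4))
  invisible(x)
}

#' Elementary model operations
#'
#' `prediction_error()` computes delta = rho * r - q, the scaled-outcome
#' prediction error. `update_q()` applies the delta rule q + eps * delta.
#' `select_learning_rate()` picks the learning-rate entry for a trial's
#' domain and prediction-error sign under the model's split structure
#' (delta = 0 ties take the positive-PE rate). `update_v()` updates the
#' Pavlovian stimulus value by v + eps * (rho * r - v), with eps chosen
#' from the stimulus prediction-error sign and rho from the trial domain.
#' All are vectorized over their numeric arguments.
#'
#' @param rho Positive outcome-impact scalar.
#' @param r Coded outcome in \{-1, 0, 1\}.
#' @param q,v Current action / stimulus value.
#' @param eps Learning rate in (0, 1).
#' @param delta Prediction error.
#' @param params A `gng_params`.
#' @param domain "gain" or "loss".
#' @export
#' @examples
#' prediction_error(rho = 2, r = -1, q = -0.5)   # -1.5
#' update_q(q = 0, eps = 0.5, delta = 1)         # 0.5
prediction_error <- function(rho, r, q) rho * r - q

#' @rdname prediction_error
#' @export
update_q <- function(q, eps, delta) q + eps * delta

#' @rdname prediction_error
#' @export
select_learning_rate <- function(params, domain, delta) {
  stopifnot(inherits(params, "gng_params"))
  loss <- domain == "loss"
  pos <- delta >= 0
  idx <- ifelse(loss, 2L, 0L) + ifelse(pos, 1L, 2L)
  unname(params$p8[idx])
}

#' @rdname prediction_error
#' @export
update_v <- function(v, params, domain, r) {
  stopifnot(inherits(params, "gng_params"))
  rho <- unname(params$p8[ifelse(domain == "loss", 6L, 5L)])
  dv <- rho * r - v
  v + select_learning_rate(params, domain, dv) * dv
}

#' Action weights and choice probability
#'
#' The go weight is Q(go, s) plus the action bias (if present) plus
#' pi * V(s) (if the Pavlovian factor is present); the no-go weight is the
#' bare Q(nogo, s). The probability of going is the two-option softmax
#' exp(w_go) / (exp(w_go) + exp(w_nogo)), evaluated in a numerically
#' stable logistic form (no overflow for |w| <= 700).
#'
#' @param q_go,q_nogo Action values for the stimulus.
#' @param v Stimulus value V(s) (ignored unless the spec has the
#'   Pavlovian factor).
#' @param params A `gng_params`.
#' @param w_go,w_nogo Action weights.
#' @return `action_weights()` a named vector (or 2-column matrix) of
#'   `w_go`, `w_nogo`; `choice_prob_go()` a probability in (0, 1).
#' @export
#' @examples
#' choice_prob_go(1, 0)   # 0.7310586
action_weights <- function(q_go, q_nogo, v, params) {
  stopifnot(inherits(params, "gng_params"))
  spec <- params$spec
  w_go <- q_go +
    (if (spec$has_bias) params$p8[["bias"]] else 0) +
    (if (spec$has_pavlovian) params$p8[["pav"]] * v else 0)
  if (length(w_go) == 1 && length(q_nogo) == 1) {
    c(w_go = unname(w_go), w_nogo = unname(q_nogo))
  } else {
    cbind(w_go = w_go, w_nogo = q_nogo)
  }
}

#' @rdname action_weights
#' @export
choice_prob_go <- function(w_go, w_nogo) {
  stats::plogis(w_go - w_nogo)
}

#' Session log-likelihood of a parameter vector
#'
#' Sums the log softmax probability of each recorded action, updating the
#' agent state after every trial: the chosen action's Q by the delta rule,
#' and (for Pavlovian models) the stimulus value V. Initial values are
#' Q = V = 0 for all stimuli and actions, the symmetric choice that makes
#' the first choice of every stimulus unbiased. The result is <= 0 and
#' equals n * log(0.5) whenever the weights stay equal.
#'
#' @param trials A trial tibble for one session (columns `trial`,
#'   `condition`, `action`, `outcome`; a `subject` column is allowed if
#'   constant).
#' @param params A `gng_params`.
#' @return The session log-likelihood (scalar).
#' @export
#' @examples
#' p <- gng_params(gng_spec(), eps = 0.3, rho = 2)
#' s <- simulate_agent(generate_schedule(10, seed = 1), p, seed = 2)
#' session_loglik(s, p)
session_loglik <- function(trials, params) {
  stopifnot(inherits(params, "gng_params"))
  if ("subject" %in% names(trials) && length(unique(trials$subject)) > 1) {
    abort("`session_loglik()` expects a single subject's session.")
  }
  trials <- validate_trials(trials, require_subject = FALSE)
  cpp_session_loglik(cond_code(trials$condition),
                     action_code(trials$action),
                     as.integer(trials$outcome),
                     unname(params$p8),
                     params$spec$has_pavlovian)
}

#' Simulate an agent on a schedule
#'
#' Forward-generative counterpart of [session_loglik()]: on each trial the
#' action is sampled from the softmax choice probability and the outcome
#' from the task's 80/20 contingency, then the state is updated exactly as
#' the likelihood assumes.
#'
#' @param schedule A schedule tibble from [generate_schedule()].
#' @param params A `gng_params`.
#' @param seed Optional integer seed (deterministic output given seed).
#' @param subject Optional subject id to attach as a column.
#' @return A trial tibble (`trial`, `condition`, `action`, `outcome`,
#'   plus `subject` if given).
#' @export
simulate_agent <- function(schedule, params, seed = NULL, subject = NULL) {
  stopifnot(inherits(params, "gng_params"))
  spec <- params$spec
  p8 <- params$p8
  s_idx <- cond_code(schedule$condition)
  n <- length(s_idx)
  with_seed(seed, {
    u_act <- runif(n)
    u_out <- runif(n)
    q <- matrix(0, nrow = 4, ncol = 2)   # columns: nogo, go
    v <- numeric(4)
    act <- integer(n)
    out <- integer(n)
    for (t in seq_len(n)) {
      s <- s_idx[t]
      loss <- s >= 3L
      w_go <- q[s, 2] + p8[["bias"]] +
        (if (spec$has_pavlovian) p8[["pav"]] * v[s] else 0)
      p_go <- stats::plogis(w_go - q[s, 1])
      a <- as.integer(u_act[t] < p_go)            # 1 go, 0 nogo
      correct <- (a == 1L) == (s %in% c(1L, 3L))
      better <- u_out[t] < (if (correct) 0.8 else 0.2)
      r <- if (loss) (if (better) 0L else -1L) else (if (better) 1L else 0L)
      rho <- p8[[if (loss) "rho_L" else "rho_G"]]
      delta <- rho * r - q[s, a + 1L]
      eps_i <- (if (loss) 2L else 0L) + (if (delta >= 0) 1L else 2L)
      q[s, a + 1L] <- q[s, a + 1L] + p8[[eps_i]] * delta
      if (spec$has_pavlovian) {
        dv <- rho * r - v[s]
        ev_i <- (if (loss) 2L else 0L) + (if (dv >= 0) 1L else 2L)
        v[s] <- v[s] + p8[[ev_i]] * dv
      }
      act[t] <- a
      out[t] <- r
    }
    res <- tibble::tibble(
      trial = schedule$trial,
      condition = schedule$condition,
      action = c("nogo", "go")[act + 1L],
      outcome = out
    )
    if (!is.null(subject)) res <- tibble::add_column(res, subject = subject,
                                                     .before = 1)
    res
  })
}
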