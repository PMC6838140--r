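test_that("spec lattice bookkeeping: parameter counts, names, strings", {
  base <- gng_spec()
  expect_equal(n_params(base), 2)
  expect_equal(param_names(base), c("eps", "rho"))
  full <- gng_spec("pe_sign_domain", rho_split = "domain", bias = TRUE,
                   pavlovian = TRUE)
  expect_equal(n_params(full), 8)
  expect_equal(spec_string(winning_spec()), "lr=4,rho=1,bias=1,pav=1")
  for (sp in all_specs()) {
    expect_equal(spec_string(parse_spec(spec_string(sp))), spec_string(sp))
  }
  expect_error(parse_spec("lr=3,rho=1,bias=0,pav=0"), "lr=3")
  expect_error(parse_spec("lr=1,rho=1,bias=0"), "pav")
  expect_error(parse_spec("lr=1,rho=1,bias=0,pavlov"), "pavlov")
})

test_that("prediction error, Q update and learning-rate selection follow the delta rule", {
  expect_equal(prediction_error(rho = 1, r = 1, q = 0), 1.0)
  expect_equal(prediction_error(rho = 1, r = 0, q = 0.3), -0.3)
  expect_equal(prediction_error(rho = 2, r = -1, q = -0.5), -1.5)

  expect_equal(update_q(q = 0, eps = 0.5, delta = 1), 0.5)
  expect_equal(update_q(q = 0.4, eps = 1e-12, delta = 3), 0.4, tolerance = 1e-9)
  # eps -> 1 limit: full update to rho * r
  expect_equal(update_q(0.2, 1 - 1e-12, prediction_error(2, -1, 0.2)), -2,
               tolerance = 1e-9)

  p4 <- winning_params()
  expect_equal(select_learning_rate(p4, "loss", 0.5), 0.330)
  expect_equal(select_learning_rate(p4, "loss", -0.5), 0.160)
  expect_equal(select_learning_rate(p4, "gain", 0.5), 0.170)
  # delta = 0 tie takes the positive-PE rate
  expect_equal(select_learning_rate(p4, "loss", 0), 0.330)

  p1 <- gng_params(gng_spec(), eps = 0.25, rho = 1)
  for (d in c("gain", "loss")) for (del in c(-1, 0, 2)) {
    expect_equal(select_learning_rate(p1, d, del), 0.25)
  }
  p2 <- gng_params(gng_spec("pe_sign"), eps_P = 0.4, eps_N = 0.1, rho = 1)
  expect_equal(select_learning_rate(p2, "gain", -2),
               select_learning_rate(p2, "loss", -2))
})

test_that("stimulus-value update follows V + eps * (rho r - V)", {
  p <- gng_params(gng_spec(pavlovian = TRUE), eps = 0.3, rho = 1, pav = 1)
  expect_equal(update_v(0, p, "gain", 1), 0.3)
  expect_equal(update_v(0.5, p, "gain", 1) , 0.5 + 0.3 * 0.5)
  # fixed point: v = rho * r
  expect_equal(update_v(1, p, "gain", 1), 1)
  p5 <- gng_params(gng_spec(pavlovian = TRUE), eps = 0.5, rho = 1, pav = 1)
  expect_equal(update_v(0, p5, "loss", -1), -0.5)
  # split-rate model: the V update picks the rate by stimulus PE sign
  p4 <- winning_params()
  expect_equal(update_v(0, p4, "loss", -1), -2 * 0.160)   # dv < 0 -> eps_LN
  expect_equal(update_v(-1, p4, "loss", 0), -1 + 0.330)   # dv > 0 -> eps_LP
})

test_that("action weights combine Q, bias and Pavlovian terms additively", {
  pb <- gng_params(gng_spec(bias = TRUE), eps = 0.2, rho = 1, bias = 0.5)
  w <- action_weights(q_go = 0, q_nogo = 0, v = 0, params = pb)
  expect_equal(unname(w), c(0.5, 0))
  # no-go weight is the bare Q whatever b and pi are
  pbp <- gng_params(gng_spec(bias = TRUE, pavlovian = TRUE),
                    eps = 0.2, rho = 1, bias = 2, pav = 3)
  w2 <- action_weights(0, 0, v = -1, params = pbp)
  expect_equal(unname(w2[["w_nogo"]]), 0)
  expect_equal(unname(w2[["w_go"]]), 2 + 3 * (-1))
  pp <- gng_params(gng_spec(pavlovian = TRUE), eps = 0.2, rho = 1, pav = 1)
  w3 <- action_weights(0.2, 0, v = -0.5, params = pp)
  expect_equal(unname(w3[["w_go"]]), -0.3)
})

test_that("choice probability is a stable two-option softmax", {
  expect_equal(choice_prob_go(0, 0), 0.5)
  for (w in c(-3, 0, 700, -700)) expect_equal(choice_prob_go(w, w), 0.5)
  expect_equal(choice_prob_go(1, 0), 1 / (1 + exp(-1)), tolerance = 1e-12)
  # shift invariance and no overflow at |w| = 700
  expect_equal(choice_prob_go(5, 3), choice_prob_go(5 + 690, 3 + 690),
               tolerance = 1e-12)
  # saturated weights stay finite (1 to double precision, never NaN/Inf)
  expect_true(is.finite(choice_prob_go(700, -700)))
  expect_gt(choice_prob_go(700, -700), 1 - 1e-10)
  expect_lt(choice_prob_go(-700, 700), 1e-10)
})

test_that("session log-likelihood matches the chance closed form in frozen models", {
  s <- random_session(3, seed = 42)
  frozen <- gng_params(gng_spec(), eps = 1e-12, rho = 1)
  expect_equal(session_loglik(s, frozen), nrow(s) * log(0.5),
               tolerance = 1e-9)
  # single trial, zero-initialized symmetric state, no bias or Pavlovian term
  one <- s[1, ]
  expect_equal(session_loglik(one, gng_params(gng_spec(), eps = 0.3, rho = 2)),
               log(0.5))
})

test_that("session log-likelihood agrees with the naive per-trial oracle", {
  specs <- all_specs()
  for (i in 1:25) {
    sp <- specs[[(i %% length(specs)) + 1]]
    par <- random_params(sp, seed = 100 + i)
    s <- random_session(3, seed = 200 + i)
    expect_equal(session_loglik(s, par),
                 oracle_loglik(as.data.frame(s), as.list(par$p8),
                               sp$has_pavlovian),
                 tolerance = 1e-12)
  }
})

test_that("nesting is exact: collapsed splits reproduce the simpler model", {
  s <- random_session(6, seed = 55)
  p_single <- gng_params(gng_spec(bias = TRUE, pavlovian = TRUE),
                         eps = 0.31, rho = 1.7, bias = 0.2, pav = 0.5)
  p_split <- gng_params(
    gng_spec("pe_sign_domain", rho_split = "domain", bias = TRUE,
             pavlovian = TRUE),
    eps_GP = 0.31, eps_GN = 0.31, eps_LP = 0.31, eps_LN = 0.31,
    rho_G = 1.7, rho_L = 1.7, bias = 0.2, pav = 0.5)
  expect_identical(session_loglik(s, p_split), session_loglik(s, p_single))
  p_pe <- gng_params(gng_spec("pe_sign", bias = TRUE, pavlovian = TRUE),
                     eps_P = 0.31, eps_N = 0.31, rho = 1.7, bias = 0.2,
                     pav = 0.5)
  expect_identical(session_loglik(s, p_pe), session_loglik(s, p_single))
})

test_that("learning on one stimulus never leaks into another", {
  # condition B trials with outcome 0 and Q0 = 0 keep delta * eps = 0, so
  # their choice probabilities stay at 0.5 and the log-likelihood
  # decomposes into the A-only session plus n_B * log(0.5)
  p <- gng_params(gng_spec(bias = FALSE), eps = 0.4, rho = 2)
  a <- random_session(4, seed = 77)
  a <- a[a$condition == "go_gain", ]
  b <- tibble::tibble(subject = "s1", trial = seq_len(4) + 100,
                      condition = "nogo_avoid",
                      action = rep(c("go", "nogo"), 2), outcome = 0L)
  both <- rbind(a, b)
  both$trial <- seq_len(nrow(both))
  expect_equal(session_loglik(both, p),
               session_loglik(a, p) + nrow(b) * log(0.5),
               tolerance = 1e-12)
})

test_that("simulated agents expose the expected behavioural structure", {
  # saturated bias: go on essentially every trial
  pb <- gng_params(gng_spec(bias = TRUE), eps = 1e-6, rho = 1, bias = 10)
  s <- simulate_agent(generate_schedule(30, seed = 1), pb, seed = 2)
  expect_gt(mean(s$action == "go"), 0.99)

  # scoring your own simulation is finite and <= 0
  p <- winning_params()
  s2 <- simulate_agent(generate_schedule(60, seed = 3), p, seed = 4)
  ll <- session_loglik(s2, p)
  expect_true(is.finite(ll) && ll <= 0)

  # determinism under seed
  expect_identical(simulate_agent(generate_schedule(10, seed = 5), p, seed = 6),
                   simulate_agent(generate_schedule(10, seed = 5), p, seed = 6))

  # learning direction: go-rate higher in go conditions than no-go ones
  set.seed(11)
  pm <- gng_params(gng_spec(), eps = 0.3, rho = 2)
  go_rates <- replicate(200, {
    sim <- simulate_agent(generate_schedule(15), pm)
    c(go = mean(sim$action[sim$condition %in% c("go_gain", "go_avoid")] == "go"),
      nogo = mean(sim$action[sim$condition %in% c("nogo_gain", "nogo_avoid")] == "go"))
  })
  expect_gt(mean(go_rates["go", ]), mean(go_rates["nogo", ]))
})

test_that("generating parameters beat perturbed ones on their own data", {
  p_true <- gng_params(gng_spec(), eps = 0.3, rho = 2)
  p_pert <- gng_params(gng_spec(), eps = 0.85, rho = 2)
  set.seed(21)
  diffs <- replicate(100, {
    s <- simulate_agent(generate_schedule(15), p_true)
    session_loglik(s, p_true) - session_loglik(s, p_pert)
  })
  expect_gt(mean(diffs), 0)
})

test_that("raising V never decreases p(go) when the Pavlovian factor is positive", {
  pp <- gng_params(gng_spec(pavlovian = TRUE), eps = 0.2, rho = 1, pav = 0.7)
  v_grid <- seq(-2, 2, length.out = 41)
  p_go <- vapply(v_grid, function(v) {
    w <- action_weights(q_go = 0.1, q_nogo = -0.2, v = v, params = pp)
    choice_prob_go(w[["w_go"]], w[["w_nogo"]])
  }, numeric(1))
  expect_true(all(diff(p_go) >= 0))
})

test_that("parameter domain violations are rejected", {
  expect_error(gng_params(gng_spec(), eps = 0, rho = 1), "\\(0, 1\\)")
  expect_error(gng_params(gng_spec(), eps = 1, rho = 1), "\\(0, 1\\)")
  expect_error(gng_params(gng_spec(), eps = 0.5, rho = -1), "positive")
  expect_error(gng_params(gng_spec(), eps = 0.5, wrong = 1), "named")
})
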