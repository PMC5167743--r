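test_that("parameter transforms round-trip and hit the canonical points", {
  expect_equal(from_transformed(rep(0, 7))$omega, 0.5)
  expect_equal(from_transformed(rep(0, 7))$beta1, 1)
  set.seed(1)
  worst <- 0
  for (i in 1:1000) {
    th <- c(rnorm(4, 0, 2), rnorm(2, 0, 1), rnorm(1))
    back <- to_transformed(from_transformed(th))
    worst <- max(worst, max(abs(unname(back) - th)))
  }
  expect_lt(worst, 1e-12)
  expect_error(to_transformed(agent_params(omega = 1)), "boundary")
  expect_error(to_transformed(agent_params(beta1 = 0)), "boundary")
})

test_that("beta splitting is the exact convex decomposition", {
  expect_equal(split_betas(0.5, 4), c(beta_mb = 2, beta_mf = 2))
  expect_equal(split_betas(0.68, 7.0),
               c(beta_mb = 4.76, beta_mf = 2.24), tolerance = 1e-12)
  set.seed(2)
  for (i in 1:50) {
    om <- runif(1); b <- runif(1, 0, 20)
    sb <- split_betas(om, b)
    expect_identical(unname(sb[1] + sb[2]), b)
  }
  p <- agent_params(omega = 0.68, beta1 = 7.67)
  expect_identical(p$beta_mb + p$beta_mf, p$beta1)
})

test_that("model-free updates follow the SARSA(lambda) trace", {
  p <- agent_params(alpha1 = 0.5, alpha2 = 0.5, lam = 0.5)
  st <- value_state()
  # fixed point: nothing to learn
  up <- mf_update(st, list(a1 = 1, state2 = 1, a2 = 1, r = 0, valid = TRUE), p)
  expect_equal(up$delta1, 0)
  expect_equal(up$delta2, 0)
  expect_equal(up$state$q1, c(0, 0))
  # direct substitution: reward of 1 on zeroed values
  up <- mf_update(value_state(),
                  list(a1 = 2, state2 = 1, a2 = 2, r = 1, valid = TRUE), p)
  expect_equal(up$delta2, 1)
  expect_equal(up$state$q2[1, 2], 0.5)
  # hand trace: stage-1 value = 0 + alpha1*delta1 + alpha1*lam*delta2 = 0.25
  expect_equal(up$state$q1[2], 0.25)
  expect_equal(up$state$q1[1], 0)
  # invalid trials change nothing
  st2 <- up$state
  up2 <- mf_update(st2, list(a1 = 1, state2 = 2, a2 = 1, r = 1,
                             valid = FALSE), p)
  expect_identical(up2$state, st2)
})

test_that("planning values weight second-stage maxima by transitions", {
  cfg <- twostep_config(p_common = 0.7)
  st <- value_state()
  st$q2 <- matrix(c(0.4, 0.1, 0.9, 0.3), 2, 2, byrow = TRUE)
  expect_equal(mb_values(st, cfg), c(0.55, 0.75))
  st$q2 <- matrix(c(1, 0, 0, 0), 2, 2, byrow = TRUE)
  expect_equal(mb_values(st, cfg), c(0.7, 0.3))
  st$q2 <- matrix(0.4, 2, 2)
  expect_equal(mb_values(st, cfg), c(0.4, 0.4))
})

test_that("hybrid values interpolate between planned and cached values", {
  cfg <- twostep_config()
  st <- value_state()
  st$q1 <- c(0.2, 0.6)
  st$q2 <- matrix(c(0.7, 0, 0.1, 0), 2, 2, byrow = TRUE)
  mbv <- mb_values(st, cfg)
  expect_equal(hybrid_values(st, agent_params(omega = 1), cfg), mbv)
  expect_equal(hybrid_values(st, agent_params(omega = 0), cfg), st$q1)
  got <- hybrid_values(st, agent_params(omega = 0.68), cfg)
  expect_equal(got, 0.68 * mbv + 0.32 * st$q1)
  # worked scalar case
  expect_equal(0.68 * 0.7 + 0.32 * 0.2, 0.54)
})

test_that("softmax probabilities are symmetric, bounded and stable", {
  expect_equal(choice_probs(c(0.3, 0.3), 5), c(0.5, 0.5))
  expect_equal(choice_probs(c(2, -1), 0), c(0.5, 0.5))
  # perseveration reduces to a logistic in beta * rho for equal values
  pr <- choice_probs(c(0.4, 0.4), 7.67, rho = 0.13, last_action = 1)
  expect_equal(pr[1], plogis(7.67 * 0.13), tolerance = 1e-12)
  # no overflow at extreme drive
  pr_big <- choice_probs(c(1000, -1000), 100)
  expect_equal(pr_big, c(1, 0))
  set.seed(3)
  for (i in 1:200) {
    pr <- choice_probs(rnorm(2), runif(1, 0, 30), rnorm(1),
                       sample(c(NA, 1, 2), 1), sample(1:2, 1))
    expect_equal(sum(pr), 1, tolerance = 1e-12)
    expect_true(all(pr >= 0))
  }
})

test_that("session likelihood matches the independent trace oracle", {
  cfg <- twostep_config()
  for (seed in 1:6) {
    tr <- make_fixture_trials(10, seed)
    pars <- random_agent(seed + 100)
    expect_equal(session_nll(tr, pars, cfg),
                 oracle_session_nll(tr, pars, cfg$p_common),
                 tolerance = 1e-10)
  }
  # uniform closed form and the empty session
  tr <- make_fixture_trials(12, 1)
  expect_equal(session_nll(tr, agent_params(beta1 = 0, beta2 = 0), cfg),
               2 * sum(tr$valid) * log(2))
  expect_equal(session_nll(tr[0, ], agent_params(), cfg), 0)
})

test_that("longer sessions also agree with the oracle", {
  cfg <- twostep_config()
  p <- agent_params(omega = 0.68, beta1 = 7.67, beta2 = 4.18, rho = 0.13)
  tr <- simulate_agent(p, cfg, seed = 21)
  expect_equal(session_nll(tr, p, cfg),
               oracle_session_nll(tr, p, cfg$p_common), tolerance = 1e-9)
})

test_that("second-stage cached values stay within the reward range", {
  cfg <- twostep_config(n_trials = 300)
  p <- random_agent(9)
  tr <- simulate_agent(p, cfg, seed = 4)
  st <- value_state()
  for (t in seq_len(nrow(tr))) {
    st <- mf_update(st, tr[t, ], p)$state
    expect_true(all(st$q2 >= 0 & st$q2 <= 1))
  }
})

test_that("agent simulation is reproducible and respects omega boundaries", {
  cfg <- twostep_config(n_trials = 60)
  p <- agent_params(omega = 0.7, beta1 = 6)
  expect_identical(simulate_agent(p, cfg, seed = 8),
                   simulate_agent(p, cfg, seed = 8))
  # omega = 0: hybrid values equal cached values on every trial (exact)
  p0 <- agent_params(omega = 0)
  tr <- simulate_agent(p0, cfg, seed = 2)
  st <- value_state()
  for (t in seq_len(nrow(tr))) {
    expect_identical(hybrid_values(st, p0, cfg), st$q1)
    st <- mf_update(st, tr[t, ], p0)$state
  }
})
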