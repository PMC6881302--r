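test_that("flat-policy likelihood has the closed form T*log(2)", {
  cfg <- task_config(n_trials = 10)
  p <- agent_params(0.5, 0, 0.5, 0.5, 0)
  sess <- simulate_agent(p, cfg, seed = 4)
  expect_equal(negative_log_likelihood(p, sess, cfg), 10 * log(2))
  # with misses, only non-missed trials contribute
  sess$missed[c(2, 5)] <- TRUE
  sess$choice[c(2, 5)] <- NA
  sess$stock[c(2, 5)] <- NA
  sess$reward[c(2, 5)] <- NA
  expect_equal(negative_log_likelihood(p, sess, cfg), 8 * log(2))
})

test_that("a single-trial session scores minus the log of one choice probability", {
  cfg <- task_config(n_trials = 2)
  params <- agent_params(0.3, 2, 0.5, 0.7, 0.4)
  sched <- matrix(c(6, 3), ncol = 2)
  sess <- make_session(0L, 1L, cfg, sched)
  probs <- choice_probabilities(value_state(cfg), params, 0, NA, cfg)
  expect_equal(negative_log_likelihood(params, sess, cfg), -log(probs[2]),
               tolerance = 1e-12)
})

test_that("degenerate sessions are rejected", {
  cfg <- task_config(n_trials = 2)
  p <- agent_params(0.5, 1, 0.5, 0.5, 0)
  empty <- simulate_agent(p, cfg, seed = 1)[0, ]
  expect_error(negative_log_likelihood(p, empty, cfg), "empty")
  allmiss <- simulate_agent(p, cfg, seed = 1)
  allmiss$missed[] <- TRUE
  expect_error(negative_log_likelihood(p, allmiss, cfg), "missed")
})

test_that("log posterior is likelihood plus prior, with uniform reduction", {
  cfg <- task_config(n_trials = 20)
  p <- agent_params(0.4, 2.5, 0.6, 0.8, 0.1)
  sess <- simulate_agent(p, cfg, seed = 6)
  nll <- negative_log_likelihood(p, sess, cfg)
  pr <- default_priors()
  expect_equal(log_posterior(p, sess, pr, cfg), -nll + log_prior(p, pr),
               tolerance = 1e-12)
  flat <- default_priors(alpha = list(dist = "uniform"),
                         beta = list(dist = "uniform"),
                         lam = list(dist = "uniform"),
                         w = list(dist = "uniform"),
                         pi = list(dist = "uniform"))
  expect_equal(log_posterior(p, sess, flat, cfg), -nll, tolerance = 1e-12)
  # higher prior density at fixed likelihood raises the posterior
  tight <- default_priors(w = list(dist = "beta", shape1 = 8, shape2 = 2))
  expect_gt(log_posterior(p, sess, tight, cfg), log_posterior(p, sess, pr, cfg))
})

test_that("MAP fits are reproducible, bounded, and internally consistent", {
  cfg <- task_config(n_trials = 60)
  gen <- agent_params(0.5, 4.2416, 0.5, 0.83, 0.15)
  sess <- simulate_agent(gen, cfg, seed = 12)
  f1 <- fit_hybrid(sess, cfg, n_restarts = 4, seed = 5)
  f2 <- fit_hybrid(sess, cfg, n_restarts = 4, seed = 5)
  expect_identical(coef(f1), coef(f2))
  cf <- coef(f1)
  expect_true(all(cf[c("alpha", "lam", "w")] >= 0 & cf[c("alpha", "lam", "w")] <= 1))
  expect_gte(cf[["beta"]], 0)
  # log-posterior identity at the optimum
  expect_equal(f1$log_posterior,
               f1$log_likelihood + log_prior(f1$params, default_priors()),
               tolerance = 1e-8)
  # the returned optimum is at least as good as every restart's endpoint
  expect_equal(min(f1$restart_objectives), -f1$log_posterior, tolerance = 1e-8)
  # advisors sharing a stock share the final model-based value
  expect_equal(f1$final_q_mb[["advisor_0"]], f1$final_q_mb[["advisor_3"]])
  expect_equal(f1$final_q_mb[["advisor_1"]], f1$final_q_mb[["advisor_2"]])
})

test_that("with an uninformative (flat-policy) session beta falls back to its prior mode", {
  cfg <- task_config()
  gen <- agent_params(0.5, 0, 0.5, 0.5, 0)
  sess <- simulate_agent(gen, cfg, seed = 13)
  f <- fit_hybrid(sess, cfg, n_restarts = 6, seed = 14)
  prior_mode <- (4.82 - 1) * 0.88
  expect_lt(abs(f$params$beta - prior_mode), 1.5)
})

test_that("final latent values come from replaying the session at the MAP estimate", {
  cfg <- task_config(n_trials = 40)
  gen <- agent_params(0.6, 3, 0.4, 0.6, 0)
  sess <- simulate_agent(gen, cfg, seed = 20)
  f <- fit_hybrid(sess, cfg, n_restarts = 3, seed = 21)
  vs <- value_state(cfg)
  for (t in seq_len(nrow(sess))) {
    vs <- update_values(vs, f$params, sess$start_state[t], sess$choice[t],
                        sess$stock[t], sess$reward[t], sess$missed[t])
  }
  expect_equal(unname(f$final_q_mf),
               c(vs$q_mf[1, 1], vs$q_mf[1, 2], vs$q_mf[2, 1], vs$q_mf[2, 2]))
  expect_equal(unname(f$final_q_mb), as.vector(t(mb_values(vs, cfg))))
})

test_that("predicted choice probabilities reproduce the likelihood", {
  cfg <- task_config(n_trials = 30)
  gen <- agent_params(0.5, 3, 0.5, 0.7, 0.1)
  sess <- simulate_agent(gen, cfg, seed = 22)
  f <- fit_hybrid(sess, cfg, n_restarts = 3, seed = 23)
  pr <- predict(f, sess)
  expect_equal(-sum(log(pr[!sess$missed])),
               -f$log_likelihood, tolerance = 1e-8)
})

test_that("parameter recovery reports sane summaries on a small cohort", {
  spec <- cohort_spec(n_subjects = 6,
                      params = list(w = list(dist = "uniform", min = 0, max = 1)))
  cfg <- task_config(n_trials = 60)
  rec <- parameter_recovery(spec, cfg, n_restarts = 2, seed = 30)
  expect_equal(nrow(rec$summary), 5)
  expect_true(all(rec$estimates$w >= 0 & rec$estimates$w <= 1))
  expect_true(is.finite(rec$summary$correlation[rec$summary$parameter == "w"]))
})
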