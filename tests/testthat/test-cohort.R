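test_that("agent parameter sampling honors points, distributions, and bounds", {
  sp_point <- cohort_spec(n_subjects = 5, params = list(w = 1))
  ags <- sample_agent_parameters(sp_point, seed = 1)
  expect_true(all(vapply(ags, function(a) a$w, numeric(1)) == 1))
  sp_unif <- cohort_spec(n_subjects = 1000,
                         params = list(w = list(dist = "uniform", min = 0, max = 1)))
  ws <- vapply(sample_agent_parameters(sp_unif, seed = 2),
               function(a) a$w, numeric(1))
  expect_lt(abs(mean(ws) - 0.5), 0.03)
  expect_true(all(ws >= 0 & ws <= 1))
  # unbounded distribution for a bounded parameter is rejected
  expect_error(cohort_spec(params = list(alpha = list(dist = "normal",
                                                      mean = 0.5, sd = 10))),
               "support exceeds")
  expect_error(cohort_spec(params = list(w = 1.5)), "bounds")
  expect_error(cohort_spec(n_subjects = 0), "n_subjects")
  expect_error(cohort_spec(miss_rate = 1), "miss_rate")
})

test_that("missed-trial injection blanks trials and skips their updates", {
  cfg <- task_config(n_trials = 40)
  p <- agent_params(0.5, 3, 0.5, 0.7, 0.1)
  sess <- simulate_agent(p, cfg, seed = 9)
  expect_identical(inject_missed_trials(sess, 0), sess)
  re <- inject_missed_trials(sess, 0.3, seed = 10)
  expect_true(any(re$missed))
  expect_true(all(is.na(re$choice[re$missed])))
  expect_true(all(is.na(re$stock[re$missed])))
  expect_true(all(is.na(re$reward[re$missed])))
  expect_true(all(!is.na(re$choice[!re$missed])))
  # same payout environment as the original session
  expect_identical(attr(re, "reward_walk"), attr(sess, "reward_walk"))
  # missed counts behave binomially
  set.seed(11)
  counts <- replicate(60, sum(inject_missed_trials(sess, 0.25)$missed))
  expect_lt(abs(mean(counts) - 10), 1.5)
})

test_that("liking ratings follow the generative value model", {
  truth <- list(list(subject_id = 1, final_q_mf = c(1, 2, 6, 7),
                     final_q_mb = c(5, 2, 2, 5), w = 0.5))
  # all coefficients zero, tiny noise: every rating is the intercept
  sp0 <- cohort_spec(liking_coeffs = c(intercept = 4, b_mb = 0, b_mf_base = 0,
                                       b_mf_w_slope = 0, noise_sd = 1e-9))
  lik0 <- generate_liking(truth, sp0, seed = 12)
  expect_equal(lik0$rating, rep(4L, 4))
  # model-based coefficient only: stock-sharing advisors tie, higher stock wins
  sp_mb <- cohort_spec(liking_coeffs = c(intercept = 4, b_mb = 2, b_mf_base = 0,
                                         b_mf_w_slope = 0, noise_sd = 1e-9))
  lik_mb <- generate_liking(truth, sp_mb, seed = 13)
  expect_equal(lik_mb$rating[1], lik_mb$rating[4])
  expect_equal(lik_mb$rating[2], lik_mb$rating[3])
  expect_gt(lik_mb$rating[1], lik_mb$rating[2])
  # ratings stay on the 1-7 scale under strong effects
  sp_big <- cohort_spec(liking_coeffs = c(intercept = 4, b_mb = 9, b_mf_base = 9,
                                          b_mf_w_slope = 0, noise_sd = 1))
  lik_big <- generate_liking(truth, sp_big, seed = 14)
  expect_true(all(lik_big$rating >= 1 & lik_big$rating <= 7))
})

test_that("low-w subjects couple ratings to model-free values more strongly", {
  set.seed(15)
  mk_truth <- function(sid, w) list(subject_id = sid,
                                    final_q_mf = runif(4, 0, 9),
                                    final_q_mb = runif(2, 0, 9)[c(1, 2, 2, 1)],
                                    w = w)
  truth <- c(lapply(1:40, function(i) mk_truth(i, 0.05)),
             lapply(41:80, function(i) mk_truth(i, 0.95)))
  sp <- cohort_spec(liking_coeffs = c(intercept = 4, b_mb = 0, b_mf_base = 0.3,
                                      b_mf_w_slope = 1.5, noise_sd = 0.3))
  lik <- generate_liking(truth, sp, seed = 16)
  slope_of <- function(ids) {
    mean(vapply(ids, function(i) {
      z <- scale(truth[[i]]$final_q_mf)[, 1]
      stats::coef(stats::lm(lik$rating[lik$subject_id == i] ~ z))[2]
    }, numeric(1)))
  }
  expect_gt(slope_of(1:40), slope_of(41:80))
})

test_that("study generation is complete, seeded, and byte-stable on disk", {
  sp <- cohort_spec(n_subjects = 3)
  cfg <- task_config(n_trials = 20)
  d1 <- withr::with_tempdir({
    study <- generate_study(sp, cfg, seed = 17, out_dir = ".")
    expect_equal(nrow(study$trials), 3 * 20)
    expect_equal(nrow(study$liking), 12)
    expect_equal(nrow(study$agents), 3)
    list(trials = readLines("trials.csv"), liking = readLines("liking.csv"),
         agents = readLines("agents.csv"))
  })
  d2 <- withr::with_tempdir({
    generate_study(sp, cfg, seed = 17, out_dir = ".")
    list(trials = readLines("trials.csv"), liking = readLines("liking.csv"),
         agents = readLines("agents.csv"))
  })
  expect_identical(d1, d2)
})

test_that("trial tables round-trip through the CSV dialect", {
  sp <- cohort_spec(n_subjects = 2, miss_rate = 0.2)
  cfg <- task_config(n_trials = 30)
  study <- generate_study(sp, cfg, seed = 18)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(study$trials, path)
  lines <- readLines(path)
  expect_equal(lines[1],
               "subject_id,trial,start_state,choice,advisor_id,stock,reward,missed")
  back <- read_trials(path)
  expect_equal(back$reward, study$trials$reward)
  expect_equal(back$missed, study$trials$missed)
  expect_equal(back$choice, study$trials$choice)
})

test_that("ground truth tables line up with the generated sessions", {
  sp <- cohort_spec(n_subjects = 4,
                    params = list(w = list(dist = "uniform", min = 0, max = 1)))
  cfg <- task_config(n_trials = 30)
  study <- generate_study(sp, cfg, seed = 19)
  tt <- truth_table(study)
  expect_equal(tt$w, study$agents$w)
  expect_equal(as.numeric(tt[2, paste0("final_q_mf_", 0:3)]),
               unname(attr(study$sessions[[2]], "final_q_mf")))
})
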