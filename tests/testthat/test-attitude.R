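# minimal fits-table-like frame with controllable values
toy_fits <- function(n_subjects, w = NULL, seed = 101) {
  set.seed(seed)
  if (is.null(w)) w <- runif(n_subjects)
  do.call(rbind, lapply(seq_len(n_subjects), function(i) {
    q2 <- runif(2, 0, 9)
    qmb <- q2[c(1, 2, 2, 1)]                 # default map pairing
    qmf <- qmb + rnorm(4, 0, 1.5)
    row <- data.frame(subject_id = i, w = w[i])
    for (k in 0:3) row[[paste0("final_q_mf_", k)]] <- qmf[k + 1]
    for (k in 0:3) row[[paste0("final_q_mb_", k)]] <- qmb[k + 1]
    row
  }))
}

toy_likings <- function(n_subjects, rating_fun) {
  do.call(rbind, lapply(seq_len(n_subjects), function(i)
    data.frame(subject_id = i, advisor_id = 0:3, rating = rating_fun(i))))
}

test_that("the attitude design standardizes within and between subjects", {
  fits <- toy_fits(10)
  lik <- toy_likings(10, function(i) c(2L, 3L, 5L, 6L))
  d <- build_attitude_design(fits, lik)
  for (sid in unique(d$subject_id)) {
    sub <- d[d$subject_id == sid, ]
    expect_lt(abs(mean(sub$mf_value_z)), 1e-10)
    expect_lt(abs(sd(sub$mf_value_z) - 1), 1e-10)
    expect_lt(abs(mean(sub$mb_value_z)), 1e-10)
    # advisors sharing a stock share the standardized model-based value
    expect_equal(sub$mb_value_z[sub$advisor_id == 0],
                 sub$mb_value_z[sub$advisor_id == 3])
    expect_equal(sub$mb_value_z[sub$advisor_id == 1],
                 sub$mb_value_z[sub$advisor_id == 2])
  }
  w_sub <- tapply(d$w_z, d$subject_id, function(x) x[1])
  expect_lt(abs(mean(w_sub)), 1e-10)
  expect_lt(abs(sd(w_sub) - 1), 1e-10)
  expect_equal(d$w_mf, d$w_z * d$mf_value_z)
})

test_that("degenerate designs are rejected or dropped", {
  fits <- toy_fits(5, w = rep(0.8, 5))
  lik <- toy_likings(5, function(i) c(2L, 3L, 5L, 6L))
  expect_error(build_attitude_design(fits, lik), "zero variance across subjects")
  fits2 <- toy_fits(5)
  fits2[1, paste0("final_q_mf_", 0:3)] <- 3  # flat values for subject 1
  expect_warning(d <- build_attitude_design(fits2, lik), "zero variance")
  expect_false(1 %in% d$subject_id)
  # liking rows without a fit are an error
  lik_bad <- rbind(lik, data.frame(subject_id = 99, advisor_id = 0, rating = 4L))
  expect_error(build_attitude_design(toy_fits(5), lik_bad), "matching fit")
})

test_that("pure-noise ratings yield near-null coefficients", {
  set.seed(202)
  fits <- toy_fits(40)
  lik <- toy_likings(40, function(i) sample(1:7, 4, TRUE))
  d <- build_attitude_design(fits, lik)
  fit <- fit_liking_model(d)
  est <- coef(fit)[c("mf_value_z", "mb_value_z", "w_z", "w_mf", "w_mb")]
  expect_true(all(abs(est) < 0.45))
  ps <- fit$coefficients$p[fit$coefficients$term != "(Intercept)"]
  expect_gt(mean(ps > 0.05), 0.5)
})

test_that("planted effects are recovered with the right signs", {
  set.seed(303)
  fits <- toy_fits(50)
  d0 <- build_attitude_design(fits, toy_likings(50, function(i) c(4L, 4L, 4L, 4L)))
  mu <- 4 + 0.6 * d0$mb_value_z + 0.5 * d0$mf_value_z - 0.4 * d0$w_mf
  d0$rating <- pmin(pmax(round(mu + rnorm(nrow(d0), 0, 0.8)), 1), 7)
  fit <- fit_liking_model(d0)
  co <- fit$coefficients
  expect_gt(co$estimate[co$term == "mb_value_z"], 0)
  expect_lt(co$p[co$term == "mb_value_z"], 0.05)
  expect_gt(co$estimate[co$term == "mf_value_z"], 0)
  expect_lt(co$estimate[co$term == "w_mf"], 0)
})

test_that("recentering at the mean reproduces the main effect exactly", {
  set.seed(404)
  fits <- toy_fits(30)
  lik <- toy_likings(30, function(i) sample(2:6, 4, TRUE))
  d <- build_attitude_design(fits, lik)
  primary <- fit_liking_model(d)
  w_raw <- attr(d, "w_raw")
  se_mean <- simple_effects(d, center = mean(w_raw))
  expect_equal(se_mean$mf_effect$estimate,
               coef(primary)[["mf_value_z"]], tolerance = 1e-8)
})

test_that("recentering shifts the simple effect by the linear algebra of moderation", {
  set.seed(505)
  fits <- toy_fits(40)
  d0 <- build_attitude_design(fits, toy_likings(40, function(i) c(4L, 4L, 4L, 4L)))
  mu <- 4 + 0.3 * d0$mb_value_z + 1.0 * d0$mf_value_z - 0.5 * d0$w_mf
  d0$rating <- mu + rnorm(nrow(d0), 0, 0.5)
  primary <- fit_liking_model(d0)
  b_mf <- coef(primary)[["mf_value_z"]]
  b_int <- coef(primary)[["w_mf"]]
  w_raw <- attr(d0, "w_raw"); w_sd <- attr(d0, "w_sd")
  center <- mean(w_raw) - w_sd  # one SD below the mean
  se <- simple_effects(d0, center = center)
  # implied simple effect: main + interaction * (center - mean)/sd = main - interaction
  expect_equal(se$mf_effect$estimate, b_mf - b_int, tolerance = 0.05)
  # the interaction coefficient is nearly unchanged by recentering (the
  # diagonal random-effect structure makes the invariance approximate)
  expect_equal(coef(se$fit)[["w_mf"]], b_int, tolerance = 0.05)
})

test_that("percentile centering uses linear interpolation of order statistics", {
  fits <- toy_fits(9, w = seq(0.1, 0.9, by = 0.1))
  lik <- toy_likings(9, function(i) c(2L, 3L, 5L, 6L))
  d <- build_attitude_design(fits, lik)
  se <- simple_effects(d, percentile = 0.25)
  expect_equal(se$center, as.numeric(quantile(seq(0.1, 0.9, 0.1), 0.25)))
  expect_error(simple_effects(d, percentile = 1.2), "percentile")
})
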