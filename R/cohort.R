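#' Specification of a synthetic study cohort
#'
#' Defines the generating conditions for a complete synthetic study:
#' how many agents, their hybrid-learner parameters (fixed values or
#' sampling distributions), the trial miss rate, and the generative
#' model of the post-task liking ratings.
#'
#' Each entry of \code{params} is either a single number (a point value
#' shared by all agents) or a distribution given as
#' \code{list(dist = "uniform", min, max)},
#' \code{list(dist = "beta", shape1, shape2)} or
#' \code{list(dist = "normal", mean, sd)}. Distributions whose support
#' exceeds the parameter's bounds (\code{[0,1]} for \code{alpha},
#' \code{lam}, \code{w}; non-negative for \code{beta}) are rejected at
#' construction.
#'
#' Liking ratings are generated from the TRUE latent values, so that
#' downstream estimation error stays attributable:
#' \deqn{r = \mathrm{clamp}(\mathrm{round}(b_0 + b_{mb} z(Q_{MB}) +
#'   (b_{mf} + b_{mf,w}(1-w)) z(Q_{MF}) + \epsilon), 1, 7)}
#' with \eqn{\epsilon \sim N(0, \sigma)} and z-scoring within subject
#' over the four advisors. The \eqn{(1-w)} moderation makes the
#' model-free coupling strongest for the most model-free subjects.
#'
#' @param n_subjects number of agents (default 65, the study's target
#'   sample size).
#' @param params named list of parameter specifications; defaults are
#'   the prior means with \code{w} at the reported group mean 0.83.
#' @param miss_rate per-trial miss probability in \code{[0, 1)}.
#' @param liking_coeffs named numeric vector \code{intercept},
#'   \code{b_mb}, \code{b_mf_base}, \code{b_mf_w_slope},
#'   \code{noise_sd}, on the 1-7 rating scale.
#' @return An object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_subjects = 65L,
                        params = list(alpha = 0.5, beta = 4.2416, lam = 0.5,
                                      w = 0.83, pi = 0.15),
                        miss_rate = 0,
                        liking_coeffs = c(intercept = 4, b_mb = 0.5,
                                          b_mf_base = 0.5, b_mf_w_slope = 0.5,
                                          noise_sd = 1)) {
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  if (miss_rate < 0 || miss_rate >= 1) stop("miss_rate must be in [0, 1)", call. = FALSE)
  need <- c("intercept", "b_mb", "b_mf_base", "b_mf_w_slope", "noise_sd")
  if (!all(need %in% names(liking_coeffs)))
    stop("liking_coeffs must name ", paste(need, collapse = ", "), call. = FALSE)
  if (liking_coeffs[["noise_sd"]] <= 0) stop("noise_sd must be > 0", call. = FALSE)
  defaults <- list(alpha = 0.5, beta = 4.2416, lam = 0.5, w = 0.83, pi = 0.15)
  for (nm in names(defaults)) if (is.null(params[[nm]])) params[[nm]] <- defaults[[nm]]
  bounds <- list(alpha = c(0, 1), lam = c(0, 1), w = c(0, 1),
                 beta = c(0, Inf), pi = c(-Inf, Inf))
  for (nm in names(bounds)) {
    sp <- params[[nm]]
    lo <- bounds[[nm]][1]; hi <- bounds[[nm]][2]
    if (is.numeric(sp) && length(sp) == 1) {
      if (sp < lo || sp > hi)
        stop(nm, " point value outside its bounds", call. = FALSE)
    } else if (is.list(sp) && !is.null(sp$dist)) {
      supp <- switch(sp$dist,
                     uniform = c(sp$min, sp$max),
                     beta = c(0, 1),
                     normal = c(-Inf, Inf),
                     stop("unknown distribution for ", nm, call. = FALSE))
      if (supp[1] < lo || supp[2] > hi)
        stop(nm, " distribution support exceeds the parameter bounds", call. = FALSE)
    } else stop("invalid specification for ", nm, call. = FALSE)
  }
  structure(list(n_subjects = as.integer(n_subjects), params = params,
                 miss_rate = miss_rate, liking_coeffs = liking_coeffs),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects, miss rate %.2f\n",
              x$n_subjects, x$miss_rate))
  for (nm in names(x$params)) {
    sp <- x$params[[nm]]
    if (is.numeric(sp)) cat(sprintf("  %-5s = %.4f\n", nm, sp))
    else cat(sprintf("  %-5s ~ %s(%s)\n", nm, sp$dist,
                     paste(unlist(sp[-1]), collapse = ", ")))
  }
  cat("  liking coefficients:",
      paste(names(x$liking_coeffs), round(x$liking_coeffs, 3),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

sample_param_1 <- function(sp) {
  if (is.numeric(sp)) return(sp)
  switch(sp$dist,
         uniform = stats::runif(1, sp$min, sp$max),
         beta = stats::rbeta(1, sp$shape1, sp$shape2),
         normal = stats::rnorm(1, sp$mean, sp$sd))
}

#' Draw agent parameter vectors for a cohort
#'
#' Point specifications yield identical vectors across agents;
#' distribution specifications sample independently per agent.
#'
#' @param spec a [cohort_spec()].
#' @param seed optional integer seed.
#' @return List of [agent_params()], length \code{n_subjects}.
#' @export
sample_agent_parameters <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(spec$n_subjects), function(i)
    agent_params(alpha = sample_param_1(spec$params$alpha),
                 beta = sample_param_1(spec$params$beta),
                 lam = sample_param_1(spec$params$lam),
                 w = sample_param_1(spec$params$w),
                 pi = sample_param_1(spec$params$pi)))
}

#' Re-simulate a session with randomly missed trials
#'
#' Marks each trial missed independently with probability
#' \code{miss_rate}, then re-runs the agent through the same payout
#' environment (the session's recorded reward walk) under that miss
#' mask, so that missed trials cause no value updates and break the
#' perseveration chain.
#'
#' @param session a session from [simulate_agent()] (its attributes
#'   carry the agent, config and reward walk).
#' @param miss_rate per-trial miss probability.
#' @param seed optional integer seed.
#' @return A new session data frame with the same attributes.
#' @export
inject_missed_trials <- function(session, miss_rate, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (miss_rate == 0) return(session)
  params <- attr(session, "agent_params")
  config <- attr(session, "config")
  walk <- attr(session, "reward_walk")
  if (is.null(params) || is.null(config) || is.null(walk))
    stop("session lacks the generative attributes needed for re-simulation",
         call. = FALSE)
  mask <- stats::runif(nrow(session)) < miss_rate
  simulate_agent(params, config, subject_id = session$subject_id[1],
                 walk = walk, miss_mask = mask)
}

#' Generate liking ratings from true latent values
#'
#' @param truth list per subject with elements \code{final_q_mf},
#'   \code{final_q_mb} (length 4) and \code{w}; as stored in the
#'   attributes of [simulate_agent()] output.
#' @param spec a [cohort_spec()] (supplies \code{liking_coeffs}).
#' @param seed optional integer seed.
#' @return Data frame \code{subject_id}, \code{advisor_id},
#'   \code{rating} (integer 1-7), 4 rows per subject.
#' @export
generate_liking <- function(truth, spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  co <- spec$liking_coeffs
  zs <- function(x) {
    s <- stats::sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  do.call(rbind, lapply(seq_along(truth), function(i) {
    tr <- truth[[i]]
    mu <- co[["intercept"]] +
      co[["b_mb"]] * zs(tr$final_q_mb) +
      (co[["b_mf_base"]] + co[["b_mf_w_slope"]] * (1 - tr$w)) * zs(tr$final_q_mf)
    raw <- mu + stats::rnorm(4, 0, co[["noise_sd"]])
    rating <- pmin(pmax(sign(raw) * floor(abs(raw) + 0.5), 1), 7)
    data.frame(subject_id = tr$subject_id, advisor_id = 0:3,
               rating = as.integer(rating))
  }))
}

#' Flatten a study's ground truth into the fits-table layout
#'
#' Gives the true generating \code{w} and true final latent values per
#' advisor in the same column layout as [fits_table()], so the attitude
#' design can be built from ground truth instead of estimates (useful
#' for generative-recovery studies where estimation error must stay
#' attributable).
#'
#' @param study a [generate_study()] result.
#' @return Data frame with \code{subject_id}, \code{w},
#'   \code{final_q_mf_0..3}, \code{final_q_mb_0..3}.
#' @export
truth_table <- function(study) {
  do.call(rbind, lapply(study$truth, function(tr) {
    row <- data.frame(subject_id = tr$subject_id, w = tr$w)
    for (i in 0:3) row[[paste0("final_q_mf_", i)]] <- tr$final_q_mf[[i + 1]]
    for (i in 0:3) row[[paste0("final_q_mb_", i)]] <- tr$final_q_mb[[i + 1]]
    row
  }))
}

#' Generate a complete synthetic study
#'
#' End-to-end emission of a study with known ground truth: sample agent
#' parameters, simulate every session (with misses), and generate
#' liking ratings from each agent's true final latent values and true
#' \code{w}.
#'
#' @param spec a [cohort_spec()].
#' @param config a [task_config()].
#' @param seed integer seed making the whole study reproducible.
#' @param out_dir optional directory; if given, writes
#'   \code{trials.csv}, \code{liking.csv} and \code{agents.csv} there.
#' @return A list with \code{trials} (all sessions, row-bound),
#'   \code{liking}, \code{agents} (ground-truth parameters), and
#'   \code{sessions} (the per-subject session list with generative
#'   attributes).
#' @export
generate_study <- function(spec = cohort_spec(), config = task_config(),
                           seed = NULL, out_dir = NULL) {
  if (!is.null(seed)) set.seed(seed)
  agents <- sample_agent_parameters(spec)
  sessions <- vector("list", spec$n_subjects)
  truth <- vector("list", spec$n_subjects)
  for (i in seq_len(spec$n_subjects)) {
    sess <- simulate_agent(agents[[i]], config, subject_id = i,
                           miss_rate = spec$miss_rate)
    sessions[[i]] <- sess
    truth[[i]] <- list(subject_id = i,
                       final_q_mf = attr(sess, "final_q_mf"),
                       final_q_mb = attr(sess, "final_q_mb"),
                       w = agents[[i]]$w)
  }
  liking <- generate_liking(truth, spec)
  agents_df <- do.call(rbind, lapply(seq_along(agents), function(i)
    data.frame(subject_id = i, alpha = agents[[i]]$alpha,
               beta = agents[[i]]$beta, lam = agents[[i]]$lam,
               w = agents[[i]]$w, pi = agents[[i]]$pi)))
  trials <- do.call(rbind, lapply(sessions, function(s) {
    for (a in c("agent_params", "final_q_mf", "final_q_mb",
                "reward_walk", "config")) attr(s, a) <- NULL
    s
  }))
  rownames(trials) <- NULL
  out <- list(trials = trials, liking = liking, agents = agents_df,
              sessions = sessions, truth = truth, spec = spec, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trials(trials, file.path(out_dir, "trials.csv"))
    write_study_csv(liking, file.path(out_dir, "liking.csv"))
    write_study_csv(agents_df, file.path(out_dir, "agents.csv"))
  }
  out
}
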