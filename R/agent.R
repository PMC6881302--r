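#' Parameters of the hybrid model-based/model-free learner
#'
#' The agent mixes two controllers at the first stage: a model-based
#' system that looks up each advisor's stock through the known
#' transition map and values the advisor by that stock's current
#' expected payoff, and a model-free system that caches values for
#' advisors (per start state and slot) and stocks from experienced
#' rewards, with a TD(lambda)-style trace carrying the second-stage
#' prediction error back to the chosen advisor.
#'
#' @param alpha learning rate in \code{[0, 1]}.
#' @param beta softmax inverse temperature, \eqn{\ge 0}.
#' @param lam eligibility-trace weight in \code{[0, 1]} with which the
#'   second-stage prediction error updates the first-stage value.
#' @param w model-based weight in \code{[0, 1]}: 0 is purely model-free,
#'   1 purely model-based.
#' @param pi choice-perseveration (stickiness) strength, unbounded; a
#'   bias toward repeating the previous first-stage slot.
#'
#' @return An object of class \code{agent_params}.
#' @examples
#' agent_params(alpha = 0.5, beta = 4.24, lam = 0.5, w = 0.83, pi = 0.15)
#' @export
agent_params <- function(alpha, beta, lam, w, pi = 0) {
  stopifnot(length(alpha) == 1, length(beta) == 1, length(lam) == 1,
            length(w) == 1, length(pi) == 1)
  if (is.na(alpha) || alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]", call. = FALSE)
  if (is.na(lam) || lam < 0 || lam > 1) stop("lam must be in [0, 1]", call. = FALSE)
  if (is.na(w) || w < 0 || w > 1) stop("w must be in [0, 1]", call. = FALSE)
  if (is.na(beta) || beta < 0) stop("beta must be non-negative", call. = FALSE)
  if (is.na(pi) || !is.finite(pi)) stop("pi must be finite", call. = FALSE)
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta),
                 lam = as.numeric(lam), w = as.numeric(w), pi = as.numeric(pi)),
            class = "agent_params")
}

#' @export
print.agent_params <- function(x, ...) {
  cat(sprintf(
    "Hybrid agent parameters: alpha = %.3f, beta = %.3f, lam = %.3f, w = %.3f, pi = %.3f\n",
    x$alpha, x$beta, x$lam, x$w, x$pi))
  invisible(x)
}

#' Fresh value state for the hybrid learner
#'
#' Model-free first-stage values \code{q_mf} (state x slot) and
#' second-stage stock values \code{q_stage2} all start at
#' \code{config$value_init} (the payout midpoint by default).
#'
#' @param config a [task_config()].
#' @return A list with \code{q_mf} (2 x 2 matrix) and \code{q_stage2}
#'   (length-2 vector).
#' @export
value_state <- function(config = task_config()) {
  list(q_mf = matrix(config$value_init, config$n_start_states, 2),
       q_stage2 = rep(config$value_init, config$n_stocks))
}

#' Model-based advisor values
#'
#' The model-based value of choosing an advisor is the current value of
#' the stock that advisor deterministically leads to; advisors mapping
#' to the same stock therefore always have identical model-based value.
#'
#' @param vs a [value_state()].
#' @param config a [task_config()].
#' @return Matrix (state x slot) of model-based values.
#' @export
mb_values <- function(vs, config) {
  matrix(vs$q_stage2[config$transition_map + 1L],
         config$n_start_states, 2)
}

#' First-stage choice probabilities
#'
#' Net advisor values mix the two controllers,
#' \eqn{V(a) = w Q_{MB}(s,a) + (1-w) Q_{MF}(s,a)}, and choices follow a
#' softmax with inverse temperature beta plus a perseveration bonus pi
#' for the slot chosen on the previous (non-missed) trial:
#' \eqn{P(a) \propto \exp(\beta V(a) + \pi \, 1[a = a_{prev}])}.
#'
#' @param vs a [value_state()].
#' @param params an [agent_params()].
#' @param state 0-based start state.
#' @param prev_slot 0-based slot chosen on the previous non-missed
#'   trial, or \code{NA} if none (start of session or after a miss).
#' @param config a [task_config()].
#' @return Numeric vector of probabilities for slots 0 and 1 (sums to 1).
#' @export
choice_probabilities <- function(vs, params, state, prev_slot = NA,
                                 config = task_config()) {
  si <- state + 1L
  qmb <- vs$q_stage2[config$transition_map[si, ] + 1L]
  v <- params$w * qmb + (1 - params$w) * vs$q_mf[si, ]
  x <- params$beta * v
  if (!is.na(prev_slot)) x[prev_slot + 1L] <- x[prev_slot + 1L] + params$pi
  x <- x - max(x)
  p <- exp(x)
  p / sum(p)
}

#' Model-free and stage-2 value update after a completed trial
#'
#' With state \eqn{s}, chosen slot \eqn{a}, reached stock \eqn{k} and
#' reward \eqn{r}: the first-stage prediction error
#' \eqn{\delta_1 = Q_2(k) - Q_{MF}(s,a)} (using the stage-2 value before
#' its own update) moves \eqn{Q_{MF}(s,a)} by \eqn{\alpha\delta_1}; the
#' reward prediction error \eqn{\delta_2 = r - Q_2(k)} moves
#' \eqn{Q_2(k)} by \eqn{\alpha\delta_2} and, weighted by the trace
#' \eqn{\lambda}, also moves \eqn{Q_{MF}(s,a)} by
#' \eqn{\alpha\lambda\delta_2}. All other entries are unchanged; missed
#' trials are a no-op.
#'
#' @param vs a [value_state()].
#' @param params an [agent_params()].
#' @param start_state,choice,stock 0-based indices of the trial.
#' @param reward experienced payout in points.
#' @param missed logical; if \code{TRUE}, values are returned unchanged.
#' @return The updated value state.
#' @export
update_values <- function(vs, params, start_state, choice, stock, reward,
                          missed = FALSE) {
  if (isTRUE(missed)) return(vs)
  si <- start_state + 1L; ai <- choice + 1L; ki <- stock + 1L
  d1 <- vs$q_stage2[ki] - vs$q_mf[si, ai]
  vs$q_mf[si, ai] <- vs$q_mf[si, ai] + params$alpha * d1
  d2 <- reward - vs$q_stage2[ki]
  vs$q_stage2[ki] <- vs$q_stage2[ki] + params$alpha * d2
  vs$q_mf[si, ai] <- vs$q_mf[si, ai] + params$alpha * params$lam * d2
  vs
}

#' Simulate one agent through a full session
#'
#' Runs the generative loop of the task: sample the balanced start-state
#' sequence, choose an advisor by [choice_probabilities()], transition
#' deterministically to its stock, emit the payout from the drifting
#' latent stock values, update values, then advance the reward walk.
#' Trials are independently missed with probability \code{miss_rate};
#' a missed trial records no choice, stock or reward, triggers no value
#' update, and breaks the perseveration chain.
#'
#' @param params an [agent_params()].
#' @param config a [task_config()].
#' @param subject_id identifier written into the records.
#' @param miss_rate probability in \code{[0, 1)} that a trial is missed.
#' @param seed optional integer seed.
#' @param walk optional precomputed latent-value matrix
#'   (\code{n_trials x n_stocks}, value in force on each trial) to replay
#'   a fixed payout environment.
#' @param miss_mask optional logical vector forcing which trials are
#'   missed (overrides \code{miss_rate}).
#'
#' @return A data frame of trial records with columns \code{subject_id},
#'   \code{trial} (0-based), \code{start_state}, \code{choice},
#'   \code{advisor_id}, \code{stock}, \code{reward}, \code{missed};
#'   missing entries are \code{NA} on missed trials. Attributes carry
#'   the ground truth: \code{"agent_params"}, \code{"final_q_mf"} and
#'   \code{"final_q_mb"} (per advisor 0..3), \code{"reward_walk"} (the
#'   latent values in force on each trial) and \code{"config"}.
#' @export
simulate_agent <- function(params, config = task_config(), subject_id = 1L,
                           miss_rate = 0, seed = NULL, walk = NULL,
                           miss_mask = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_trials
  states <- generate_start_state_sequence(config)
  if (is.null(walk)) {
    init <- config$reward_init
    if (is.null(init))
      init <- stats::runif(config$n_stocks, config$reward_min, config$reward_max)
    walk <- matrix(NA_real_, n, config$n_stocks)
    cur <- init
    for (t in seq_len(n)) {
      walk[t, ] <- cur
      cur <- step_reward_walk(cur, config)
      attr(cur, "increments") <- NULL
    }
  }
  if (is.null(miss_mask)) {
    miss_mask <- if (miss_rate > 0) stats::runif(n) < miss_rate else rep(FALSE, n)
  }
  vs <- value_state(config)
  choice <- stock <- rep(NA_integer_, n)
  reward <- rep(NA_real_, n)
  prev_slot <- NA_integer_
  for (t in seq_len(n)) {
    if (miss_mask[t]) { prev_slot <- NA_integer_; next }
    s <- states[t]
    p <- choice_probabilities(vs, params, s, prev_slot, config)
    a <- if (stats::runif(1) < p[1]) 0L else 1L
    k <- transition(s, a, config)
    r <- emit_payout(walk[t, ], k, config)
    vs <- update_values(vs, params, s, a, k, r)
    choice[t] <- a; stock[t] <- k; reward[t] <- r
    prev_slot <- a
  }
  rec <- data.frame(
    subject_id = subject_id,
    trial = seq_len(n) - 1L,
    start_state = states,
    choice = choice,
    advisor_id = ifelse(is.na(choice), NA_integer_, advisor_id(states, choice)),
    stock = stock,
    reward = reward,
    missed = miss_mask
  )
  qmb <- mb_values(vs, config)
  attr(rec, "agent_params") <- params
  attr(rec, "final_q_mf") <- as.vector(t(vs$q_mf))   # advisor order 0..3
  attr(rec, "final_q_mb") <- as.vector(t(qmb))
  attr(rec, "reward_walk") <- walk
  attr(rec, "config") <- config
  rec
}
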