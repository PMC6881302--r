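#' Task configuration for the social two-step task
#'
#' Builds the structural and stochastic constants of the task: two
#' first-stage states (advisor pairs), four advisors, two second-stage
#' stocks reached deterministically from the chosen advisor, and stock
#' payouts that drift as a Gaussian random walk with reflecting bounds.
#'
#' All identifiers in trial records are 0-based: start states are
#' \code{0/1}, advisor slots \code{0/1}, global advisor ids
#' \code{0..3} (\code{state * 2 + slot}), stocks \code{0/1}, trials
#' \code{0..n_trials-1}. The default transition map sends, from state 0,
#' slot 0 to stock 0 and slot 1 to stock 1; from state 1 the mapping is
#' crossed (slot 0 to stock 1, slot 1 to stock 0), so each stock is
#' reachable from both states and each state maps one advisor to each
#' stock.
#'
#' @param n_trials number of main-task trials (default 150), must be
#'   divisible by \code{n_start_states}.
#' @param n_start_states number of first-stage states (2).
#' @param n_advisors number of advisors (4, two per start state).
#' @param n_stocks number of second-stage stocks (2).
#' @param walk_sd standard deviation, in points, of the Gaussian
#'   random-walk increments of each stock's latent value (default 2).
#' @param reward_min,reward_max reflecting bounds of the walk in points
#'   (defaults 0 and 9).
#' @param transition_map integer matrix \code{n_start_states x 2} giving
#'   the 0-based stock reached from each (state, slot); must map one
#'   advisor to each stock within every state.
#' @param reward_init optional numeric vector of initial latent stock
#'   values; if \code{NULL} they are drawn uniformly on
#'   \code{[reward_min, reward_max]} at simulation time.
#' @param integer_payouts if \code{TRUE} (default) payouts are the latent
#'   value rounded half-away-from-zero to an integer; otherwise the
#'   continuous latent value is paid out.
#' @param value_init initial Q-value for all advisor and stock values
#'   (default the payout midpoint, 4.5).
#'
#' @return An object of class \code{task_config} (a named list).
#' @examples
#' cfg <- task_config()
#' transition(0, 0, cfg)
#' @export
task_config <- function(n_trials = 150L, n_start_states = 2L, n_advisors = 4L,
                        n_stocks = 2L, walk_sd = 2, reward_min = 0,
                        reward_max = 9, transition_map = NULL,
                        reward_init = NULL, integer_payouts = TRUE,
                        value_init = NULL) {
  if (walk_sd <= 0) stop("walk_sd must be positive", call. = FALSE)
  if (reward_min >= reward_max) stop("reward_min must be < reward_max", call. = FALSE)
  if (n_trials %% n_start_states != 0)
    stop("n_trials must be divisible by n_start_states", call. = FALSE)
  if (is.null(transition_map)) {
    transition_map <- matrix(c(0L, 1L, 1L, 0L), nrow = 2, byrow = TRUE)
  }
  transition_map <- matrix(as.integer(transition_map), nrow = n_start_states)
  for (s in seq_len(n_start_states)) {
    if (!setequal(transition_map[s, ], seq_len(n_stocks) - 1L))
      stop("transition_map must map one advisor to each stock within every start state",
           call. = FALSE)
  }
  for (k in seq_len(n_stocks) - 1L) {
    if (!all(apply(transition_map, 1, function(row) k %in% row)))
      stop("each stock must be reachable from every start state", call. = FALSE)
  }
  if (is.null(value_init)) value_init <- (reward_min + reward_max) / 2
  if (!is.null(reward_init)) {
    reward_init <- as.numeric(reward_init)
    if (length(reward_init) != n_stocks ||
        any(reward_init < reward_min | reward_init > reward_max))
      stop("reward_init must give one value in [reward_min, reward_max] per stock",
           call. = FALSE)
  }
  structure(list(
    n_trials = as.integer(n_trials), n_start_states = as.integer(n_start_states),
    n_advisors = as.integer(n_advisors), n_stocks = as.integer(n_stocks),
    walk_sd = walk_sd, reward_min = reward_min, reward_max = reward_max,
    transition_map = transition_map, reward_init = reward_init,
    integer_payouts = isTRUE(integer_payouts), value_init = value_init
  ), class = "task_config")
}

#' @export
print.task_config <- function(x, ...) {
  cat("Two-step task configuration\n")
  cat(sprintf("  %d trials, %d start states, %d advisors, %d stocks\n",
              x$n_trials, x$n_start_states, x$n_advisors, x$n_stocks))
  cat(sprintf("  reward walk: SD %.2f, reflecting bounds [%g, %g], %s payouts\n",
              x$walk_sd, x$reward_min, x$reward_max,
              if (x$integer_payouts) "integer" else "continuous"))
  cat("  transition map (state x slot -> stock):\n")
  print(x$transition_map)
  invisible(x)
}

# reflect a scalar into [lo, hi] by mirroring at the violated bound
reflect_into <- function(x, lo, hi) {
  while (x < lo || x > hi) {
    if (x > hi) x <- 2 * hi - x else x <- 2 * lo - x
  }
  x
}

#' Advance the stock-reward random walk one step
#'
#' Each stock's latent value receives an independent Gaussian increment
#' (mean 0, SD \code{walk_sd}) and is then reflected into
#' \code{[reward_min, reward_max]} by mirroring at the violated bound,
#' repeated until in range. Consumes the current R random-number stream.
#'
#' @param values numeric vector of current latent values, one per stock.
#' @param config a [task_config()].
#' @return The new latent values, with the raw pre-reflection Gaussian
#'   increments attached as attribute \code{"increments"}.
#' @export
step_reward_walk <- function(values, config) {
  if (config$walk_sd <= 0) stop("walk_sd must be positive", call. = FALSE)
  inc <- stats::rnorm(length(values), 0, config$walk_sd)
  out <- values + inc
  for (i in seq_along(out)) {
    out[i] <- reflect_into(out[i], config$reward_min, config$reward_max)
  }
  attr(out, "increments") <- inc
  out
}

#' Simulate the reward random walk for many steps
#'
#' @param n_steps number of steps.
#' @param config a [task_config()].
#' @param init optional initial latent values; defaults to
#'   \code{config$reward_init}, or uniform draws on the bounds if that is
#'   \code{NULL}.
#' @param seed optional integer seed.
#' @return A list with \code{values} (matrix \code{n_steps x n_stocks} of
#'   post-reflection latent values) and \code{increments} (matrix of the
#'   raw Gaussian increments).
#' @export
simulate_reward_walk <- function(n_steps, config = task_config(), init = NULL,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init)) init <- config$reward_init
  if (is.null(init))
    init <- stats::runif(config$n_stocks, config$reward_min, config$reward_max)
  vals <- matrix(NA_real_, n_steps, config$n_stocks)
  incs <- matrix(NA_real_, n_steps, config$n_stocks)
  cur <- init
  for (t in seq_len(n_steps)) {
    cur <- step_reward_walk(cur, config)
    incs[t, ] <- attr(cur, "increments")
    attr(cur, "increments") <- NULL
    vals[t, ] <- cur
  }
  list(values = vals, increments = incs)
}

#' Payout emitted by a stock
#'
#' Returns the stock's current latent value; with integer payouts it is
#' rounded half-away-from-zero to an integer (so 6.5 pays 7).
#'
#' @param values latent values per stock.
#' @param stock 0-based stock id.
#' @param config a [task_config()].
#' @return Payout in points.
#' @export
emit_payout <- function(values, stock, config) {
  v <- values[stock + 1L]
  if (config$integer_payouts) sign(v) * floor(abs(v) + 0.5) else v
}

#' Balanced random sequence of first-stage states
#'
#' Trials are split evenly between the start states; the order is a
#' uniform random permutation of the balanced multiset.
#'
#' @param config a [task_config()].
#' @param seed optional integer seed.
#' @return Integer vector of 0-based start states, length
#'   \code{n_trials}.
#' @export
generate_start_state_sequence <- function(config = task_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (config$n_trials %% config$n_start_states != 0)
    stop("n_trials must be divisible by n_start_states", call. = FALSE)
  states <- rep(seq_len(config$n_start_states) - 1L,
                each = config$n_trials %/% config$n_start_states)
  sample(states)
}

#' Deterministic advisor-to-stock transition
#'
#' @param start_state 0-based first-stage state.
#' @param choice 0-based advisor slot within the state.
#' @param config a [task_config()].
#' @return 0-based stock id. Pure lookup; no randomness.
#' @export
transition <- function(start_state, choice, config) {
  if (any(start_state < 0 | start_state >= config$n_start_states) ||
      any(choice < 0 | choice > 1))
    stop("invalid start_state or choice", call. = FALSE)
  config$transition_map[cbind(start_state + 1L, choice + 1L)]
}

#' Global advisor identifier
#'
#' Advisors are numbered \code{0..3} as \code{start_state * 2 + slot}.
#'
#' @param start_state 0-based state.
#' @param choice 0-based slot.
#' @return 0-based advisor id.
#' @export
advisor_id <- function(start_state, choice) {
  as.integer(start_state) * 2L + as.integer(choice)
}
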