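# Independent brute-force oracle for the hybrid model likelihood.
#
# Recomputes session probabilities from first principles with its own
# arithmetic (no package internals): chains softmax choice probabilities
# and value updates trial by trial, and enumerates every possible choice
# sequence of a short session to give the full probability tree.

# probability of slot 1 (index 1..2) given explicit value bookkeeping
oracle_step_prob <- function(q2, qmf, s, prev, alpha, beta, lam, w, ppi, map) {
  qmb <- c(q2[map[s, 1] + 1], q2[map[s, 2] + 1])
  v <- w * qmb + (1 - w) * qmf[s, ]
  x <- beta * v
  if (!is.na(prev)) x[prev] <- x[prev] + ppi
  e <- exp(x - max(x))
  e / sum(e)
}

# value update; the trace term uses the stage-2 value BEFORE its own
# reward update (both prediction errors computed up front)
oracle_update <- function(q2, qmf, s, a, k, r, alpha, lam) {
  d1 <- q2[k + 1] - qmf[s, a]
  d2 <- r - q2[k + 1]
  qmf[s, a] <- qmf[s, a] + alpha * d1 + alpha * lam * d2
  q2[k + 1] <- q2[k + 1] + alpha * d2
  list(q2 = q2, qmf = qmf)
}

# negative log-likelihood of the observed choices by direct chaining
oracle_nll <- function(params, session, config) {
  map <- config$transition_map
  q2 <- rep(config$value_init, 2)
  qmf <- matrix(config$value_init, 2, 2)
  prev <- NA
  nll <- 0
  for (t in seq_len(nrow(session))) {
    if (session$missed[t]) { prev <- NA; next }
    s <- session$start_state[t] + 1
    a <- session$choice[t] + 1
    p <- oracle_step_prob(q2, qmf, s, prev, params$alpha, params$beta,
                          params$lam, params$w, params$pi, map)
    nll <- nll - log(p[a])
    up <- oracle_update(q2, qmf, s, a, session$stock[t], session$reward[t],
                        params$alpha, params$lam)
    q2 <- up$q2; qmf <- up$qmf
    prev <- a
  }
  nll
}

# probability of every choice sequence of a short session, enumerated
# over the full generative tree. start_states: 0-based vector;
# reward_schedule: matrix n_trials x 2 (payout each stock would give).
oracle_tree <- function(params, start_states, reward_schedule, config) {
  map <- config$transition_map
  n <- length(start_states)
  seqs <- as.matrix(expand.grid(rep(list(0:1), n)))[, n:1, drop = FALSE]
  probs <- apply(seqs, 1, function(choices) {
    q2 <- rep(config$value_init, 2)
    qmf <- matrix(config$value_init, 2, 2)
    prev <- NA
    pr <- 1
    for (t in seq_len(n)) {
      s <- start_states[t] + 1
      a <- choices[t] + 1
      p <- oracle_step_prob(q2, qmf, s, prev, params$alpha, params$beta,
                            params$lam, params$w, params$pi, map)
      pr <- pr * p[a]
      k <- map[s, a]
      up <- oracle_update(q2, qmf, s, a, k, reward_schedule[t, k + 1],
                          params$alpha, params$lam)
      q2 <- up$q2; qmf <- up$qmf
      prev <- a
    }
    pr
  })
  list(sequences = seqs, probabilities = probs)
}

# build a fully explicit 3-trial session data frame from choices
make_session <- function(start_states, choices, config,
                         reward_schedule, missed = NULL) {
  n <- length(start_states)
  if (is.null(missed)) missed <- rep(FALSE, n)
  stock <- reward <- rep(NA_real_, n)
  for (t in seq_len(n)) {
    if (missed[t]) next
    stock[t] <- config$transition_map[start_states[t] + 1, choices[t] + 1]
    reward[t] <- reward_schedule[t, stock[t] + 1]
  }
  data.frame(subject_id = 1L, trial = seq_len(n) - 1L,
             start_state = start_states,
             choice = ifelse(missed, NA_integer_, choices),
             advisor_id = ifelse(missed, NA_integer_,
                                 start_states * 2L + choices),
             stock = ifelse(missed, NA_integer_, as.integer(stock)),
             reward = reward, missed = missed)
}
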