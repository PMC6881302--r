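#' Exclude subjects by missed-trial rate
#'
#' A subject is excluded when the proportion of missed trials is
#' strictly greater than the threshold (default 20%); a rate of exactly
#' the threshold is retained.
#'
#' @param trials multi-subject trial data frame.
#' @param threshold miss-proportion cutoff (default 0.20).
#' @return List with \code{included} (subject ids), \code{excluded},
#'   and \code{report} (per-subject miss rates).
#' @export
exclusion_filter <- function(trials, threshold = 0.20) {
  if (nrow(trials) == 0) stop("no trials", call. = FALSE)
  rates <- tapply(trials$missed, trials$subject_id, mean)
  report <- data.frame(subject_id = names(rates),
                       miss_rate = as.numeric(rates),
                       excluded = as.numeric(rates) > threshold,
                       row.names = NULL)
  # keep subject ids in their original type
  ids <- unique(trials$subject_id)
  report$subject_id <- ids[match(report$subject_id, as.character(ids))]
  list(included = report$subject_id[!report$excluded],
       excluded = report$subject_id[report$excluded],
       report = report)
}

#' Code stay/switch rows for the lagged regression
#'
#' For each trial with a usable predecessor, codes whether the subject
#' returned to the same second-stage stock as on the most recent
#' non-missed trial (stay = 1), whether the two trials began in the
#' same first-stage state (+1 same, -1 different), and the reward
#' earned on that previous trial, z-scored within subject over the
#' included rows. The interaction column is the product of the two
#' standardized predictors. Rows whose current trial is missed are
#' dropped; a missed trial's predecessor role falls to the last
#' non-missed trial before it.
#'
#' @param trials multi-subject trial data frame (already filtered by
#'   [exclusion_filter()] if desired).
#' @return Data frame of class \code{stay_table}: \code{subject_id},
#'   \code{trial}, \code{stay}, \code{prev_reward_z},
#'   \code{same_state}, \code{interaction}. Subjects with zero variance
#'   in previous reward are dropped with a warning.
#' @export
code_stay_switch <- function(trials) {
  per_subject <- split(trials, trials$subject_id)
  rows <- lapply(per_subject, function(sess) {
    sess <- sess[order(sess$trial), ]
    n <- nrow(sess)
    if (n < 2) return(NULL)
    out <- vector("list", n)
    prev <- NA_integer_  # row index of most recent non-missed trial
    for (t in seq_len(n)) {
      if (!sess$missed[t] && !is.na(prev)) {
        out[[t]] <- data.frame(
          subject_id = sess$subject_id[t],
          trial = sess$trial[t],
          stay = as.integer(sess$stock[t] == sess$stock[prev]),
          prev_reward = sess$reward[prev],
          same_state = ifelse(sess$start_state[t] == sess$start_state[prev],
                              1, -1))
      }
      if (!sess$missed[t]) prev <- t
    }
    do.call(rbind, out[!vapply(out, is.null, logical(1))])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  keep <- vapply(rows, function(d) stats::sd(d$prev_reward) > 0, logical(1))
  if (any(!keep)) {
    warning("dropping subject(s) with zero variance in previous reward: ",
            paste(vapply(rows[!keep], function(d) as.character(d$subject_id[1]),
                         character(1)), collapse = ", "), call. = FALSE)
    rows <- rows[keep]
  }
  if (length(rows) == 0) return(structure(data.frame(), class = c("stay_table", "data.frame")))
  tab <- do.call(rbind, lapply(rows, function(d) {
    d$prev_reward_z <- (d$prev_reward - mean(d$prev_reward)) / stats::sd(d$prev_reward)
    d
  }))
  tab$interaction <- tab$prev_reward_z * tab$same_state
  tab <- tab[, c("subject_id", "trial", "stay", "prev_reward_z",
                 "same_state", "interaction")]
  rownames(tab) <- NULL
  class(tab) <- c("stay_table", "data.frame")
  tab
}

#' Hierarchical logistic regression of stay behavior
#'
#' Fits \code{stay ~ prev_reward_z + same_state + interaction} with a
#' subject-level random intercept and uncorrelated random slopes for
#' all three predictors (variance-only random effects), by Laplace
#' approximation via \code{lme4::glmer}. A positive previous-reward
#' main effect is the model-based signature (reward drives returning to
#' a stock from either start state); a positive reward-by-same-state
#' interaction is the model-free signature (reward drives repetition
#' specifically when the same advisors reappear).
#'
#' If the mixed model fails outright, the documented fallback fits
#' per-subject logistic regressions and tests each coefficient across
#' subjects with one-sample t tests; \code{method} records which path
#' ran.
#'
#' @param table a \code{stay_table} from [code_stay_switch()].
#' @return Object of class \code{stay_fit}: \code{coefficients}
#'   (estimate, se, z, p), \code{ranef_variances}, \code{converged},
#'   \code{method} ("glmer-laplace" or "per-subject"), and the
#'   underlying model object when available.
#' @export
fit_stay_model <- function(table) {
  if (length(unique(table$subject_id)) < 2)
    stop("need at least 2 subjects", call. = FALSE)
  if (stats::var(table$stay) == 0)
    stop("stay outcome is constant (complete separation); the stay model ",
         "cannot be fit", call. = FALSE)
  warns <- character(0)
  fit <- withCallingHandlers(
    tryCatch(
      lme4::glmer(
        stay ~ prev_reward_z + same_state + interaction +
          (1 + prev_reward_z + same_state + interaction || subject_id),
        data = table, family = stats::binomial(),
        control = lme4::glmerControl(calc.derivs = FALSE)),
      error = function(e) e),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (!inherits(fit, "error")) {
    sm <- suppressWarnings(summary(fit))$coefficients
    coefs <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                        z = sm[, 3], p = sm[, 4], row.names = NULL)
    vc <- lme4::VarCorr(fit)
    rv <- unlist(lapply(vc, function(m) diag(m)))
    msgs <- c(fit@optinfo$conv$lme4$messages, warns)
    structure(list(coefficients = coefs,
                   ranef_variances = rv,
                   converged = length(msgs) == 0,
                   convergence_messages = msgs,
                   method = "glmer-laplace", model = fit),
              class = "stay_fit")
  } else {
    per <- lapply(split(table, table$subject_id), function(d) {
      tryCatch(stats::coef(stats::glm(
        stay ~ prev_reward_z + same_state + interaction,
        data = d, family = stats::binomial())), error = function(e) NULL)
    })
    mat <- do.call(rbind, per[!vapply(per, is.null, logical(1))])
    coefs <- do.call(rbind, lapply(colnames(mat), function(tm) {
      x <- mat[, tm]
      tt <- stats::t.test(x)
      data.frame(term = tm, estimate = mean(x),
                 se = stats::sd(x) / sqrt(length(x)),
                 z = unname(tt$statistic), p = tt$p.value)
    }))
    structure(list(coefficients = coefs, ranef_variances = NULL,
                   converged = FALSE,
                   convergence_messages = conditionMessage(fit),
                   method = "per-subject", model = NULL),
              class = "stay_fit")
  }
}

#' @export
print.stay_fit <- function(x, ...) {
  cat(sprintf("Stay/switch lagged logistic regression (%s%s)\n", x$method,
              if (x$converged) "" else "; convergence flagged"))
  print(x$coefficients, row.names = FALSE, digits = 3)
  if (!is.null(x$ranef_variances)) {
    cat("Random-effect variances (subject):\n")
    print(round(x$ranef_variances, 4))
  }
  invisible(x)
}

#' @export
coef.stay_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' Stay probabilities in the reward-by-state 2x2 layout
#'
#' Per-subject stay proportions in the four cells formed by whether the
#' previous trial's reward was above that subject's median (high/low)
#' and whether the start state repeated (same/different), then cell
#' means with within-subject-adjusted standard errors
#' (Cousineau-Morey: subject-centered values, SE scaled by
#' \eqn{\sqrt{k/(k-1)}} for \eqn{k = 4} cells).
#'
#' @param trials multi-subject trial data frame.
#' @return Object of class \code{stay_prob_table}: \code{cells}
#'   (cell means, adjusted SEs, subject counts) and
#'   \code{per_subject} (the subject-by-cell proportions).
#' @export
stay_probability_table <- function(trials) {
  tab_rows <- lapply(split(trials, trials$subject_id), function(sess) {
    sess <- sess[order(sess$trial), ]
    n <- nrow(sess)
    prev <- NA_integer_
    recs <- NULL
    for (t in seq_len(n)) {
      if (!sess$missed[t] && !is.na(prev)) {
        recs <- rbind(recs, data.frame(
          stay = as.integer(sess$stock[t] == sess$stock[prev]),
          prev_reward = sess$reward[prev],
          same = sess$start_state[t] == sess$start_state[prev]))
      }
      if (!sess$missed[t]) prev <- t
    }
    if (is.null(recs) || nrow(recs) == 0) return(NULL)
    med <- stats::median(recs$prev_reward)
    recs$high <- recs$prev_reward > med
    agg <- stats::aggregate(stay ~ high + same, data = recs, FUN = mean)
    agg$subject_id <- sess$subject_id[1]
    agg
  })
  per <- do.call(rbind, tab_rows[!vapply(tab_rows, is.null, logical(1))])
  per$cell <- paste0(ifelse(per$high, "high", "low"), "_",
                     ifelse(per$same, "same", "different"))
  # Cousineau-Morey adjustment over subjects with all four cells
  counts <- table(per$subject_id)
  complete <- names(counts)[counts == 4]
  pc <- per[as.character(per$subject_id) %in% complete, ]
  grand <- mean(pc$stay)
  subj_means <- tapply(pc$stay, pc$subject_id, mean)
  pc$centered <- pc$stay - subj_means[as.character(pc$subject_id)] + grand
  k <- 4
  cells <- do.call(rbind, lapply(sort(unique(per$cell)), function(cl) {
    all_vals <- per$stay[per$cell == cl]
    cen <- pc$centered[pc$cell == cl]
    data.frame(cell = cl, mean = mean(all_vals),
               se_adjusted = stats::sd(cen) / sqrt(length(cen)) * sqrt(k / (k - 1)),
               n_subjects = length(all_vals))
  }))
  structure(list(cells = cells, per_subject = per,
                 n_complete = length(complete)),
            class = "stay_prob_table")
}

#' @export
print.stay_prob_table <- function(x, ...) {
  cat("Stay probability by previous reward (high/low) and start state (same/different):\n")
  print(x$cells, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Plot the reward-by-state stay probabilities
#'
#' Base-graphics rendering of the 2x2 stay-probability layout: one line
#' per start-state condition across low/high previous reward, with
#' within-subject-adjusted error bars.
#'
#' @param x a \code{stay_prob_table}.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.stay_prob_table <- function(x, ...) {
  cells <- x$cells
  get <- function(cl, col) cells[cells$cell == cl, col]
  m <- rbind(same = c(get("low_same", "mean"), get("high_same", "mean")),
             different = c(get("low_different", "mean"), get("high_different", "mean")))
  se <- rbind(c(get("low_same", "se_adjusted"), get("high_same", "se_adjusted")),
              c(get("low_different", "se_adjusted"), get("high_different", "se_adjusted")))
  graphics::matplot(t(m), type = "b", pch = c(19, 17), lty = 1:2, col = c(1, 2),
                    xaxt = "n", xlab = "Previous reward", xlim = c(0.75, 2.25),
                    ylab = "P(stay with same stock)", ylim = c(0, 1), ...)
  graphics::axis(1, at = 1:2, labels = c("low", "high"))
  for (i in 1:2) graphics::arrows(1:2, t(m)[, i] - t(se)[, i],
                                  1:2, t(m)[, i] + t(se)[, i],
                                  angle = 90, code = 3, length = 0.04,
                                  col = c(1, 2)[i])
  graphics::legend("bottomright", legend = c("same state", "different state"),
                   pch = c(19, 17), lty = 1:2, col = c(1, 2), bty = "n")
  invisible(x)
}
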