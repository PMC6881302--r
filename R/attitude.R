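#' Build the liking-regression design matrix
#'
#' Joins each subject's final latent advisor values to their liking
#' ratings and applies the standardization scheme of the attitude
#' analysis: model-free and model-based values are z-scored within
#' subject (over the four advisors), the model-based weight \code{w} is
#' z-scored across subjects, and the interaction columns are products
#' of the standardized columns.
#'
#' @param fits fits table (from [fits_table()]) or any data frame with
#'   \code{subject_id}, \code{w}, \code{final_q_mf_0..3},
#'   \code{final_q_mb_0..3}. Ground-truth values (e.g. from
#'   [generate_study()]'s \code{agents}/truth) can be supplied the same
#'   way.
#' @param likings data frame \code{subject_id}, \code{advisor_id},
#'   \code{rating}.
#' @return Data frame of class \code{attitude_design} with columns
#'   \code{subject_id}, \code{advisor_id}, \code{rating},
#'   \code{mf_value_z}, \code{mb_value_z}, \code{w_z}, \code{w_mf},
#'   \code{w_mb}; attributes \code{w_raw} (named per-subject raw w) and
#'   \code{w_sd}. Subjects with zero variance in a value regressor are
#'   dropped with a warning; zero variance in \code{w} across subjects
#'   is an error.
#' @export
build_attitude_design <- function(fits, likings) {
  need <- c("subject_id", "w", paste0("final_q_mf_", 0:3), paste0("final_q_mb_", 0:3))
  if (!all(need %in% names(fits)))
    stop("fits must contain columns ", paste(need, collapse = ", "), call. = FALSE)
  if (!all(likings$subject_id %in% fits$subject_id))
    stop("every liking row needs a matching fit", call. = FALSE)
  rows <- lapply(seq_len(nrow(fits)), function(i) {
    sid <- fits$subject_id[i]
    lk <- likings[likings$subject_id == sid, ]
    if (nrow(lk) == 0) return(NULL)
    qmf <- as.numeric(fits[i, paste0("final_q_mf_", 0:3)])
    qmb <- as.numeric(fits[i, paste0("final_q_mb_", 0:3)])
    if (stats::sd(qmf) == 0 || stats::sd(qmb) == 0) {
      warning("dropping subject ", sid,
              ": zero variance in a value regressor", call. = FALSE)
      return(NULL)
    }
    data.frame(subject_id = sid,
               advisor_id = lk$advisor_id,
               rating = lk$rating,
               mf_value_z = ((qmf - mean(qmf)) / stats::sd(qmf))[lk$advisor_id + 1L],
               mb_value_z = ((qmb - mean(qmb)) / stats::sd(qmb))[lk$advisor_id + 1L],
               w_raw = fits$w[i])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) stop("no usable subjects", call. = FALSE)
  d <- do.call(rbind, rows)
  w_by_subject <- tapply(d$w_raw, d$subject_id, function(x) x[1])
  w_sd <- stats::sd(w_by_subject)
  if (is.na(w_sd) || w_sd == 0)
    stop("w has zero variance across subjects; w_z is undefined", call. = FALSE)
  w_mean <- mean(w_by_subject)
  d$w_z <- (d$w_raw - w_mean) / w_sd
  d$w_mf <- d$w_z * d$mf_value_z
  d$w_mb <- d$w_z * d$mb_value_z
  rownames(d) <- NULL
  attr(d, "w_raw") <- w_by_subject
  attr(d, "w_sd") <- w_sd
  attr(d, "w_mean") <- w_mean
  class(d) <- c("attitude_design", "data.frame")
  d
}

liking_formula <- stats::as.formula(
  "rating ~ mf_value_z + mb_value_z + w_z + w_mf + w_mb + (1 + mf_value_z + mb_value_z + w_mf + w_mb || subject_id)")

liking_fit_from_design <- function(design) {
  warns <- character(0)
  fit <- withCallingHandlers(
    tryCatch(
      lmerTest::lmer(liking_formula, data = design,
                     control = lme4::lmerControl(calc.derivs = FALSE,
                                                 check.conv.singular = "ignore")),
      error = function(e) e),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (inherits(fit, "error")) {
    return(structure(list(coefficients = NULL, converged = FALSE,
                          convergence_messages = conditionMessage(fit),
                          method = "lmer-reml", model = NULL),
                     class = "liking_fit"))
  }
  sm <- suppressWarnings(summary(fit))$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                      se = sm[, "Std. Error"], df = sm[, "df"],
                      t = sm[, "t value"], p = sm[, "Pr(>|t|)"],
                      row.names = NULL)
  vc <- lme4::VarCorr(fit)
  msgs <- c(fit@optinfo$conv$lme4$messages, warns)
  structure(list(coefficients = coefs,
                 ranef_variances = unlist(lapply(vc, function(m) diag(m))),
                 residual_sd = attr(vc, "sc"),
                 converged = length(msgs) == 0,
                 convergence_messages = msgs,
                 logLik = as.numeric(stats::logLik(fit)),
                 method = "lmer-reml", model = fit),
            class = "liking_fit")
}

#' Hierarchical regression of liking ratings on latent values
#'
#' Mixed-effects linear regression of post-task liking ratings on final
#' model-free values, final model-based values, the model-based weight
#' \code{w}, and the interaction of \code{w} with each type of value
#' (all standardized per [build_attitude_design()]); subject-level
#' random intercept and uncorrelated random slopes for the
#' within-subject predictors (variance-only). Fit by REML with
#' Satterthwaite degrees of freedom via \code{lmerTest}.
#'
#' Because the within-subject regressors are standardized, the value
#' main effects are read at the cohort-mean \code{w}; [simple_effects()]
#' recenters them at other points of the \code{w} distribution.
#'
#' @param design an [build_attitude_design()] result.
#' @return Object of class \code{liking_fit}: \code{coefficients}
#'   (estimate, se, df, t, p), \code{ranef_variances},
#'   \code{converged}, and the fitted \code{lmerMod}.
#' @export
fit_liking_model <- function(design) {
  if (length(unique(design$subject_id)) < 2)
    stop("need at least 2 subjects", call. = FALSE)
  liking_fit_from_design(design)
}

#' @export
print.liking_fit <- function(x, ...) {
  cat(sprintf("Liking ~ latent values mixed regression (%s%s)\n", x$method,
              if (isTRUE(x$converged)) "" else "; convergence flagged"))
  if (!is.null(x$coefficients)) print(x$coefficients, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
coef.liking_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' Simple effect of model-free value at a percentile of w
#'
#' Recomputes the \code{w} regressor centered at the stated percentile
#' of the raw fitted \code{w} distribution (linear-interpolation
#' quantile), keeping the original scale (division by the cohort SD of
#' \code{w}), rebuilds the interaction columns, refits the liking
#' model, and reports the model-free value coefficient at that center.
#' Centering at the cohort mean (\code{percentile = NULL},
#' \code{center = mean}) reproduces the primary fit's main effect.
#'
#' @param design an [build_attitude_design()] result.
#' @param percentile probability in (0, 1) at which to center \code{w};
#'   ignored when \code{center} is given.
#' @param center optional explicit raw-scale center.
#' @return Object of class \code{simple_effect}: the recentered
#'   \code{center} (raw w), the \code{mf} coefficient row (estimate,
#'   se, df, t, p), and the full refit.
#' @export
simple_effects <- function(design, percentile = NULL, center = NULL) {
  w_raw <- attr(design, "w_raw")
  w_sd <- attr(design, "w_sd")
  if (is.null(center)) {
    if (is.null(percentile) || percentile <= 0 || percentile >= 1)
      stop("percentile must be in (0, 1)", call. = FALSE)
    center <- as.numeric(stats::quantile(w_raw, percentile, type = 7))
  }
  d <- design
  d$w_z <- (d$w_raw - center) / w_sd
  d$w_mf <- d$w_z * d$mf_value_z
  d$w_mb <- d$w_z * d$mb_value_z
  refit <- liking_fit_from_design(d)
  mf_row <- refit$coefficients[refit$coefficients$term == "mf_value_z", ]
  structure(list(center = center, percentile = percentile,
                 mf_effect = mf_row, fit = refit),
            class = "simple_effect")
}

#' @export
print.simple_effect <- function(x, ...) {
  cat(sprintf("Simple effect of model-free value at w = %.3f%s:\n", x$center,
              if (!is.null(x$percentile))
                sprintf(" (%.0fth percentile)", 100 * x$percentile) else ""))
  print(x$mf_effect, row.names = FALSE, digits = 3)
  invisible(x)
}
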