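#' Write a trial table to CSV
#'
#' Columns, in order: \code{subject_id, trial, start_state, choice,
#' advisor_id, stock, reward, missed}; missing values are written as
#' empty fields; header row mandatory; UTF-8 with LF line endings.
#' \code{missed} is written as 0/1.
#'
#' @param trials trial data frame.
#' @param path output file.
#' @export
write_trials <- function(trials, path) {
  cols <- c("subject_id", "trial", "start_state", "choice", "advisor_id",
            "stock", "reward", "missed")
  out <- trials[, cols]
  out$missed <- as.integer(out$missed)
  write_study_csv(out, path)
}

#' Read a trial table from CSV
#'
#' @param path file written by [write_trials()].
#' @return Trial data frame with \code{missed} as logical and empty
#'   fields as \code{NA}.
#' @export
read_trials <- function(path) {
  d <- utils::read.csv(path, na.strings = "")
  d$missed <- as.logical(d$missed)
  d
}

# shared CSV writer: no quotes, empty string for NA, LF endings
write_study_csv <- function(d, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(d, con, sep = ",", quote = FALSE, na = "",
                     row.names = FALSE, eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a task configuration from a YAML file
#'
#' Keys mirror the arguments of [task_config()]; \code{transition_map}
#' may be given as a flat row-major vector of 0-based stock ids.
#'
#' @param path YAML file.
#' @return A [task_config()].
#' @export
read_task_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$transition_map))
    y$transition_map <- matrix(as.integer(unlist(y$transition_map)),
                               nrow = if (is.null(y$n_start_states)) 2L
                                      else y$n_start_states, byrow = TRUE)
  do.call(task_config, y)
}

#' Read a prior specification from a YAML file
#'
#' Each top-level key (\code{alpha}, \code{beta}, \code{lam}, \code{w},
#' \code{pi}) holds \code{dist} plus its hyperparameters, as in
#' [default_priors()].
#'
#' @param path YAML file.
#' @return A \code{prior_spec}.
#' @export
read_priors <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(default_priors, y)
}
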