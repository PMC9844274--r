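#' Score trial records
#'
#' Adds the trial-level error — the absolute distance between the true
#' ensemble mean and the chosen probe, in feature units — and a correctness
#' flag (`correct = 1` iff the error is zero). Both the true mean and the
#' response must belong to the task's probe set.
#'
#' @param trials A tibble with columns `observer_id`, `task`, `trial`,
#'   `true_mean`, `response`.
#' @return The input with `error` and `correct` columns added or replaced.
#' @export
#' @examples
#' score_trials(tibble::tibble(
#'   observer_id = 1, task = "length", trial = 1:2,
#'   true_mean = c(80, 56), response = c(80, 68)
#' ))
score_trials <- function(trials) {
  required <- c("observer_id", "task", "trial", "true_mean", "response")
  missing <- setdiff(required, names(trials))
  if (length(missing) > 0) {
    stop("trials is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad_task <- setdiff(unique(trials$task), c("length", "orientation"))
  if (length(bad_task) > 0) {
    stop("unknown task value(s): ", paste(bad_task, collapse = ", "),
         call. = FALSE)
  }
  for (tk in unique(trials$task)) {
    probes <- probe_set(tk)
    rows <- which(trials$task == tk)
    for (col in c("true_mean", "response")) {
      off <- rows[!trials[[col]][rows] %in% probes]
      if (length(off) > 0) {
        stop(sprintf(
          "%s values outside the %s probe set {%s} in row(s) %s (e.g. %s)",
          col, tk, paste(probes, collapse = ", "),
          paste(head(off, 5), collapse = ", "), trials[[col]][off[1]]
        ), call. = FALSE)
      }
    }
  }
  dplyr::mutate(
    tibble::as_tibble(trials),
    error = abs(.data$response - .data$true_mean),
    correct = as.integer(.data$error == 0)
  )
}

#' Per-participant summary scores
#'
#' Aggregates scored trials into the per-participant, per-task measures of
#' the analysis: proportion correct, mean absolute error, the SD of signed
#' errors (chosen minus true; the robustness measure, sensitive to bias) and,
#' secondarily, the SD of absolute errors.
#'
#' @param trials A scored trial tibble (see [score_trials()]; unscored input
#'   is scored first).
#' @return A tibble with one row per `observer_id` x `task`: `n_trials`,
#'   `accuracy`, `mean_abs_error`, `sd_error`, `sd_abs_error`.
#' @export
score_participants <- function(trials) {
  if (!all(c("error", "correct") %in% names(trials))) {
    trials <- score_trials(trials)
  }
  dplyr::summarise(
    dplyr::group_by(trials, .data$observer_id, .data$task),
    n_trials = dplyr::n(),
    accuracy = mean(.data$correct),
    mean_abs_error = mean(.data$error),
    sd_error = sd(.data$response - .data$true_mean),
    sd_abs_error = sd(.data$error),
    .groups = "drop"
  )
}
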