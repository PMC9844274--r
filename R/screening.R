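#' Trial difficulty (easiness) from above-chance participants
#'
#' For each task, the proportion of correct responses on each trial computed
#' over only those participants whose whole-task accuracy exceeds chance
#' (1/5 for a 5-AFC task). Below-chance participants never influence the
#' difficulty vector.
#'
#' @param trials A scored trial tibble.
#' @param chance Chance accuracy level (default 0.2); above-chance means
#'   strictly greater.
#' @return A tibble with columns `task`, `trial`, `difficulty`,
#'   `n_above_chance`.
#' @export
trial_difficulty <- function(trials, chance = 0.2) {
  if (!all(c("error", "correct") %in% names(trials))) {
    trials <- score_trials(trials)
  }
  acc <- dplyr::summarise(
    dplyr::group_by(trials, .data$observer_id, .data$task),
    accuracy = mean(.data$correct), .groups = "drop"
  )
  above <- dplyr::filter(acc, .data$accuracy > chance)
  if (any(!unique(trials$task) %in% above$task)) {
    missing <- setdiff(unique(trials$task), above$task)
    stop("no above-chance participants on task(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sub <- dplyr::semi_join(trials, above, by = c("observer_id", "task"))
  dplyr::summarise(
    dplyr::group_by(sub, .data$task, .data$trial),
    difficulty = mean(.data$correct),
    n_above_chance = dplyr::n(),
    .groups = "drop"
  )
}

#' Person fit to trial difficulty
#'
#' Pearson correlation between a participant's per-trial correctness (1/0)
#' and the trial difficulty vector of the task. A positive correlation — the
#' participant succeeds where above-chance participants succeed — is evidence
#' of effort even when overall accuracy is poor. Undefined (NA) when either
#' vector is constant, e.g. an all-incorrect participant.
#'
#' @param trials A scored trial tibble.
#' @param difficulty Output of [trial_difficulty()]; computed from `trials`
#'   if omitted.
#' @param chance Chance level used when `difficulty` must be computed.
#' @return A tibble with columns `observer_id`, `task`, `person_fit`.
#' @export
person_fit <- function(trials, difficulty = NULL, chance = 0.2) {
  if (!all(c("error", "correct") %in% names(trials))) {
    trials <- score_trials(trials)
  }
  if (is.null(difficulty)) difficulty <- trial_difficulty(trials, chance)
  joined <- dplyr::inner_join(trials, difficulty, by = c("task", "trial"))
  dplyr::summarise(
    dplyr::group_by(joined, .data$observer_id, .data$task),
    person_fit = if (sd(.data$correct) == 0 || sd(.data$difficulty) == 0) {
      NA_real_
    } else {
      cor(.data$correct, .data$difficulty)
    },
    .groups = "drop"
  )
}

#' Apply the participant-inclusion rule
#'
#' A participant is included if they are above chance (accuracy strictly
#' greater than `chance`) on both tasks, or if, on every task where they are
#' at or below chance, their person-fit correlation with trial difficulty is
#' at least `fit_threshold`. An undefined person fit (constant correctness)
#' fails the criterion. Manual exclusions (technical difficulty, misread
#' instructions) are supplied as an ID list.
#'
#' @param trials A scored trial tibble covering both tasks.
#' @param chance Chance accuracy (default 0.2).
#' @param fit_threshold Minimum person-fit correlation (default 0.15).
#' @param manual_exclude Optional vector of observer IDs excluded a priori.
#' @return A tibble with one row per observer: per-task accuracies,
#'   above-chance flags, person-fit values, `included`, and a `reason` code
#'   (`above-chance-both`, `rescued-by-person-fit`, `below-fit-threshold`,
#'   `manual`).
#' @export
screen_participants <- function(trials, chance = 0.2, fit_threshold = 0.15,
                                manual_exclude = NULL) {
  if (!all(c("error", "correct") %in% names(trials))) {
    trials <- score_trials(trials)
  }
  scores <- score_participants(trials)
  fits <- person_fit(trials, chance = chance)

  wide <- tidyr::pivot_wider(
    dplyr::select(scores, "observer_id", "task", "accuracy"),
    names_from = "task", values_from = "accuracy", names_prefix = "accuracy_"
  )
  fitw <- tidyr::pivot_wider(
    fits, names_from = "task", values_from = "person_fit", names_prefix = "fit_"
  )
  rep <- dplyr::left_join(wide, fitw, by = "observer_id")
  rep <- dplyr::mutate(
    rep,
    above_chance_length = .data$accuracy_length > chance,
    above_chance_orientation = .data$accuracy_orientation > chance,
    fit_ok_length = .data$above_chance_length |
      (!is.na(.data$fit_length) & .data$fit_length >= fit_threshold),
    fit_ok_orientation = .data$above_chance_orientation |
      (!is.na(.data$fit_orientation) & .data$fit_orientation >= fit_threshold),
    included = (.data$above_chance_length & .data$above_chance_orientation) |
      (.data$fit_ok_length & .data$fit_ok_orientation),
    reason = dplyr::case_when(
      above_chance_length & above_chance_orientation ~ "above-chance-both",
      included ~ "rescued-by-person-fit",
      TRUE ~ "below-fit-threshold"
    )
  )
  if (!is.null(manual_exclude)) {
    rep <- dplyr::mutate(
      rep,
      included = .data$included & !.data$observer_id %in% manual_exclude,
      reason = dplyr::if_else(.data$observer_id %in% manual_exclude,
                              "manual", .data$reason)
    )
  }
  dplyr::select(rep, "observer_id", "accuracy_length", "accuracy_orientation",
                "above_chance_length", "above_chance_orientation",
                "fit_length", "fit_orientation", "included", "reason")
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability of a cases-by-items score matrix:
#' alpha = k/(k-1) * (1 - sum of item variances / variance of case totals).
#'
#' @param x A numeric matrix or data frame, rows = cases (participants),
#'   columns = items (trials).
#' @return A list with `alpha`, `n_items`, `n_cases`.
#' @export
#' @examples
#' m <- matrix(rnorm(50), nrow = 10)
#' cronbach_alpha(m + rnorm(10))  # shared case effect raises alpha
cronbach_alpha <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2) {
    stop("need at least 2 cases and 2 items", call. = FALSE)
  }
  if (anyNA(x)) stop("missing cells are not supported", call. = FALSE)
  k <- ncol(x)
  total_var <- var(rowSums(x))
  if (total_var == 0) {
    stop("zero variance of case totals: alpha undefined", call. = FALSE)
  }
  alpha <- k / (k - 1) * (1 - sum(apply(x, 2, var)) / total_var)
  list(alpha = alpha, n_items = k, n_cases = nrow(x))
}

#' Reliability of the trial-level error measure per task
#'
#' Treats each trial's absolute error as an item and computes Cronbach's
#' alpha over the (included) participants, per task. This is the reliability
#' that bounds the observable across-task correlation of mean absolute
#' errors and feeds the attenuation correction.
#'
#' @param trials A scored trial tibble.
#' @param include Optional vector of observer IDs to keep (e.g. the included
#'   set from [screen_participants()]).
#' @return A tibble with columns `task`, `alpha`, `n_items`, `n_cases`.
#' @export
task_reliability <- function(trials, include = NULL) {
  if (!all(c("error", "correct") %in% names(trials))) {
    trials <- score_trials(trials)
  }
  if (!is.null(include)) {
    trials <- dplyr::filter(trials, .data$observer_id %in% include)
  }
  purrr::map_dfr(sort(unique(trials$task)), function(tk) {
    wide <- tidyr::pivot_wider(
      dplyr::select(dplyr::filter(trials, .data$task == tk),
                    "observer_id", "trial", "error"),
      names_from = "trial", values_from = "error"
    )
    a <- cronbach_alpha(dplyr::select(wide, -"observer_id"))
    tibble::tibble(task = tk, alpha = a$alpha, n_items = a$n_items,
                   n_cases = a$n_cases)
  })
}
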