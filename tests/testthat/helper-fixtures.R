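# Shared fixtures, built in code at test time.

# A deterministic hand-built two-task trial table with full experimenter
# control over each observer's correctness pattern.
#
# pattern: named list observer_id -> list(length = <correct trial indices>,
# orientation = <correct trial indices>). Incorrect responses are the probe
# one step above the true mean (wrapping down at the top probe).
make_patterned_trials <- function(pattern, n_trials = 120) {
  one_task <- function(task) {
    probes <- probe_set(task)
    true <- rep(probes, length.out = n_trials)
    wrong <- ifelse(true == probes[5], probes[4],
                    probes[match(true, probes) + 1])
    purrr::map_dfr(names(pattern), function(id) {
      correct_idx <- pattern[[id]][[task]]
      resp <- wrong
      resp[correct_idx] <- true[correct_idx]
      tibble::tibble(
        observer_id = as.integer(id), task = task,
        trial = seq_len(n_trials), true_mean = true, response = resp
      )
    })
  }
  score_trials(dplyr::bind_rows(one_task("length"), one_task("orientation")))
}

# Five diligent reference observers, correct on trials 1..90 of both tasks:
# their accuracy is 0.75 and the induced difficulty vector is 1 on trials
# 1..90 and 0 on 91..120.
reference_pattern <- function() {
  p <- lapply(1:5, function(i) list(length = 1:90, orientation = 1:90))
  names(p) <- as.character(100 + 1:5)
  p
}

# Correlation of mean absolute errors across tasks for one simulated cohort,
# after applying the inclusion rule.
cohort_error_correlation <- function(seed, params = cohort_params(seed = seed)) {
  trials <- simulate_study(params)
  scores <- score_participants(trials)
  screening <- screen_participants(trials)
  inc <- dplyr::filter(scores,
                       .data$observer_id %in%
                         screening$observer_id[screening$included])
  wide <- tidyr::pivot_wider(
    dplyr::select(inc, "observer_id", "task", "mean_abs_error"),
    names_from = "task", values_from = "mean_abs_error"
  )
  list(r = stats::cor(wide$length, wide$orientation), wide = wide,
       screening = screening)
}

# Monte-Carlo Bayes factor oracle: average likelihood ratio over iid draws
# from the one-sided stretched-beta prior (folding a symmetric draw onto
# (0, 1)). Independent of the quadrature path in bf_plus0().
mc_bf_plus0 <- function(r, n, kappa = 1, n_draws = 1e5) {
  rho <- abs(2 * stats::rbeta(n_draws, 1 / kappa, 1 / kappa) - 1)
  mean(exp(lineens:::log_lik_ratio(rho, r, n)))
}
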