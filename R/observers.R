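#' Cohort parameters for the synthetic observer population
#'
#' Describes a population of noisy-averaging 5-AFC observers. Each observer
#' carries an internal noise SD per task; the pair of log noise SDs is drawn
#' from a bivariate normal whose correlation `rho_ability` is the single knob
#' controlling shared ability across the two averaging tasks. A `lapse_rate`
#' fraction of trials are answered uniformly at random, and a `p_inattentive`
#' fraction of observers ignore the stimulus entirely (uniform responding on
#' every trial) — the known-truth target for the screening stage.
#'
#' The defaults are a calibrated preset for a cohort of 77 attentive
#' observers: internal-noise locations and spreads were chosen (via the
#' closed-form accuracy of the nearest-probe observer, then confirmed by
#' simulation) so that marginal accuracies, mean absolute errors, and the
#' across-task correlation of mean absolute errors (~0.65) match the study
#' conditions this package models. See the methods vignette for the
#' calibration.
#'
#' @param n_observers Number of observers (default 77).
#' @param rho_ability Correlation of log internal noise across tasks.
#' @param mu_log_sigma_length,mu_log_sigma_orientation Mean of log internal
#'   noise (log px / log degrees).
#' @param tau_length,tau_orientation Between-observer SD of log internal noise.
#' @param lapse_rate Per-trial probability of a uniform random response.
#' @param p_inattentive Fraction of observers responding uniformly at random.
#' @param seed Integer seed used by [draw_observers()] and [simulate_study()].
#' @return A list of class `cohort_params`.
#' @export
#' @examples
#' cohort_params(n_observers = 10, seed = 1)
cohort_params <- function(n_observers = 77,
                          rho_ability = 0.71,
                          mu_log_sigma_length = log(15.8),
                          mu_log_sigma_orientation = log(13.4),
                          tau_length = 0.45,
                          tau_orientation = 0.5,
                          lapse_rate = 0.02,
                          p_inattentive = 0,
                          seed = NULL) {
  stopifnot(
    n_observers >= 1,
    abs(rho_ability) <= 1,
    tau_length >= 0, tau_orientation >= 0,
    lapse_rate >= 0, lapse_rate <= 1,
    p_inattentive >= 0, p_inattentive <= 1
  )
  structure(
    list(
      n_observers = as.integer(n_observers),
      rho_ability = rho_ability,
      mu_log_sigma_length = mu_log_sigma_length,
      mu_log_sigma_orientation = mu_log_sigma_orientation,
      tau_length = tau_length,
      tau_orientation = tau_orientation,
      lapse_rate = lapse_rate,
      p_inattentive = p_inattentive,
      seed = seed
    ),
    class = "cohort_params"
  )
}

#' @export
print.cohort_params <- function(x, ...) {
  cat("<cohort_params>\n")
  cat("  observers:", x$n_observers,
      if (x$p_inattentive > 0) sprintf("(p_inattentive = %.2f)", x$p_inattentive),
      "\n")
  cat(sprintf("  log internal noise: length N(%.3f, %.2f), orientation N(%.3f, %.2f), rho = %.2f\n",
              x$mu_log_sigma_length, x$tau_length,
              x$mu_log_sigma_orientation, x$tau_orientation, x$rho_ability))
  cat(sprintf("  lapse rate: %.3f, seed: %s\n", x$lapse_rate,
              x$seed %||% "<none>"))
  invisible(x)
}

#' Draw individual observers from a cohort
#'
#' Samples per-observer internal-noise SDs from the cohort's bivariate
#' log-normal ability distribution and flags inattentive observers.
#'
#' @param params A [cohort_params()] object.
#' @param seed Optional seed overriding `params$seed`.
#' @return A tibble with one row per observer: `observer_id`, `sigma_length`,
#'   `sigma_orientation`, `lapse_rate`, `inattentive`.
#' @export
draw_observers <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "cohort_params"))
  draw <- function() {
    n <- params$n_observers
    z1 <- rnorm(n)
    z2 <- params$rho_ability * z1 +
      sqrt(1 - params$rho_ability^2) * rnorm(n)
    tibble::tibble(
      observer_id = seq_len(n),
      sigma_length = exp(params$mu_log_sigma_length + params$tau_length * z1),
      sigma_orientation = exp(params$mu_log_sigma_orientation +
                                params$tau_orientation * z2),
      lapse_rate = params$lapse_rate,
      inattentive = rbinom(n, 1, params$p_inattentive) == 1
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulate 5-AFC responses of noisy-averaging observers
#'
#' The generative response model: with probability `lapse` (always, for an
#' inattentive observer) the response is a uniformly random probe; otherwise
#' the internal estimate is `true_mean` plus Gaussian noise with SD `sigma`,
#' and the response is the probe nearest the estimate (midpoint ties resolve
#' to the lower probe).
#'
#' All arguments except `probes` are recycled to a common length, so one call
#' can simulate many observers and trials at once.
#'
#' @param true_mean True ensemble mean(s) of the trial(s).
#' @param sigma Internal noise SD(s), same units as `true_mean`.
#' @param probes The task's 5 probe values (see [probe_set()]).
#' @param lapse Lapse probability per trial.
#' @param inattentive Logical; forces uniform responding.
#' @return Numeric vector of chosen probe values.
#' @export
#' @examples
#' simulate_responses(rep(80, 5), sigma = 0.001, probes = probe_set("length"))
simulate_responses <- function(true_mean, sigma, probes,
                               lapse = 0, inattentive = FALSE) {
  if (length(probes) == 0) stop("empty probe set", call. = FALSE)
  probes <- sort(probes)
  n <- max(length(true_mean), length(sigma), length(lapse), length(inattentive))
  true_mean <- rep_len(true_mean, n)
  sigma <- rep_len(sigma, n)
  lapse <- rep_len(lapse, n)
  inattentive <- rep_len(inattentive, n)

  est <- true_mean + rnorm(n, 0, sigma)
  mids <- (probes[-length(probes)] + probes[-1]) / 2
  # ties at a midpoint go to the lower probe
  idx <- findInterval(est, mids, left.open = TRUE) + 1L
  chosen <- probes[idx]

  guess <- inattentive | (stats::runif(n) < lapse)
  if (any(guess)) {
    chosen[guess] <- sample(probes, sum(guess), replace = TRUE)
  }
  chosen
}

#' Simulate a full two-task study for a cohort
#'
#' Every observer completes 120 trials of the length-averaging task followed
#' by 120 trials of the orientation-averaging task, all in the same fixed
#' trial order. Responses follow [simulate_responses()].
#'
#' @param cohort A [cohort_params()] object, or a tibble of observers from
#'   [draw_observers()].
#' @param length_design,orientation_design Design tibbles from
#'   [task_design()]; defaults use the design's natural order.
#' @param seed Integer seed (defaults to the cohort's).
#' @return A trial-record tibble: `observer_id`, `task`, `trial`, `true_mean`,
#'   `response`, `error`, `correct`.
#' @export
#' @examples
#' trials <- simulate_study(cohort_params(n_observers = 4, seed = 1))
simulate_study <- function(cohort,
                           length_design = task_design("length"),
                           orientation_design = task_design("orientation"),
                           seed = NULL) {
  if (nrow(length_design) == 0 || nrow(orientation_design) == 0) {
    stop("empty task design", call. = FALSE)
  }
  if (inherits(cohort, "cohort_params")) seed <- seed %||% cohort$seed
  run <- function() {
    observers <- if (inherits(cohort, "cohort_params")) {
      draw_observers(cohort, seed = NULL)     # inside the seeded stream
    } else {
      cohort
    }
    one_task <- function(design, sigma_col) {
      true <- dplyr::pull(design, paste0("mean_", design$task[1]))
      grid <- tidyr::expand_grid(
        observer_id = observers$observer_id,
        trial = design$trial
      )
      grid$true_mean <- rep(true, times = nrow(observers))
      sig <- observers[[sigma_col]][match(grid$observer_id, observers$observer_id)]
      lap <- observers$lapse_rate[match(grid$observer_id, observers$observer_id)]
      inat <- observers$inattentive[match(grid$observer_id, observers$observer_id)]
      grid$response <- simulate_responses(
        grid$true_mean, sig, probe_set(design$task[1]),
        lapse = lap, inattentive = inat
      )
      grid$task <- design$task[1]
      grid
    }
    out <- dplyr::bind_rows(
      one_task(length_design, "sigma_length"),
      one_task(orientation_design, "sigma_orientation")
    )
    out <- dplyr::select(out, "observer_id", "task", "trial", "true_mean",
                         "response")
    score_trials(out)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
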