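#' Study configuration
#'
#' Bundles every tunable of the pipeline into one validated list: the design
#' realization settings, the observer cohort, the screening thresholds, the
#' prior, and the sequential design. The configuration round-trips through
#' JSON losslessly and is hashed into every report for provenance.
#'
#' @param cohort A [cohort_params()] object.
#' @param version Counterbalanced layout version to realize (1-5).
#' @param n_versions Number of layout versions to generate.
#' @param sd_tol Ensemble SD tolerance (feature units).
#' @param max_restarts Restart budget for the ensemble sampler.
#' @param chance Chance accuracy for screening (default 0.2).
#' @param fit_threshold Person-fit inclusion threshold (default 0.15).
#' @param kappa Prior width for the correlation analysis.
#' @param n_start,bf_high,bf_low Sequential design parameters.
#' @param seed Master seed for the run.
#' @return A list of class `study_config`.
#' @export
study_config <- function(cohort = cohort_params(),
                         version = 1, n_versions = 5,
                         sd_tol = 0.5, max_restarts = 100,
                         chance = 0.2, fit_threshold = 0.15,
                         kappa = 1,
                         n_start = 75, bf_high = 3, bf_low = 1 / 3,
                         seed = 1) {
  stopifnot(inherits(cohort, "cohort_params"),
            version >= 1, version <= n_versions,
            chance > 0, chance < 1, kappa > 0)
  structure(
    list(
      cohort = cohort, version = as.integer(version),
      n_versions = as.integer(n_versions),
      sd_tol = sd_tol, max_restarts = max_restarts,
      chance = chance, fit_threshold = fit_threshold,
      kappa = kappa, n_start = n_start, bf_high = bf_high, bf_low = bf_low,
      seed = as.integer(seed)
    ),
    class = "study_config"
  )
}

#' Run the full pipeline: design, simulate, score, screen, analyze
#'
#' Orchestrates every stage end to end: realizes both task designs for the
#' configured version, simulates the cohort, scores trials and participants,
#' applies the inclusion rule, estimates per-task reliability over the
#' included participants, and runs the Bayesian correlation and sequential
#' analyses on the included set. With `out_dir` the stage artifacts are
#' written as `design.json`, `trials.csv`, `scores.csv`, `screening.json` and
#' `result.json`; identical seed and config give byte-identical payloads.
#'
#' @param config A [study_config()].
#' @param out_dir Optional directory for the artifact bundle.
#' @param quiet Suppress per-stage log lines.
#' @return (Invisibly) a list with `design`, `trials`, `scores`, `screening`,
#'   `reliability`, `correlation` (an `ens_cor`), `sequential` (an `ens_seq`
#'   or NULL), and `config_hash`.
#' @export
#' @examples
#' res <- run_study(study_config(cohort_params(n_observers = 20, seed = 2)))
#' tidy(res$correlation)
run_study <- function(config = study_config(), out_dir = NULL, quiet = TRUE) {
  stopifnot(inherits(config, "study_config"))
  say <- function(stage, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  hash <- rlang::hash(unclass_config(config))
  seed <- config$seed

  layouts <- build_layouts(config$n_versions, seed = seed)
  layout_for <- function(tk) {
    dplyr::select(
      dplyr::filter(layouts, .data$version == config$version, .data$task == tk),
      "line", "row", "col"
    )
  }
  designs <- list(
    length = task_design("length", seed = seed),
    orientation = task_design("orientation", seed = seed + 1L)
  )
  design <- dplyr::bind_rows(
    realize_design(designs$length, layout_for("length"),
                   sd_tol = config$sd_tol, max_restarts = config$max_restarts,
                   seed = seed + 2L),
    realize_design(designs$orientation, layout_for("orientation"),
                   sd_tol = config$sd_tol, max_restarts = config$max_restarts,
                   seed = seed + 3L)
  )
  say("design", "realized %d line records (%d trials)", nrow(design),
      nrow(design) / 12)

  trials <- simulate_study(config$cohort, designs$length, designs$orientation,
                           seed = seed + 4L)
  say("simulate", "%d trial records from %d observers", nrow(trials),
      config$cohort$n_observers)

  scores <- score_participants(trials)
  screening <- screen_participants(trials, chance = config$chance,
                                   fit_threshold = config$fit_threshold)
  included <- screening$observer_id[screening$included]
  say("screen", "%d of %d observers included", length(included),
      nrow(screening))

  # degenerate cohorts (e.g. zero error variance) have undefined reliability
  reliability <- tryCatch(task_reliability(trials, include = included),
                          error = function(e) NULL)
  rel <- if (!is.null(reliability)) {
    as.list(stats::setNames(reliability$alpha, reliability$task))
  }

  inc_scores <- dplyr::filter(scores, .data$observer_id %in% included)
  correlation <- correlate_tasks(inc_scores, kappa = config$kappa,
                                 reliabilities = rel)
  say("analyze", "r = %.3f, BF+0 = %.3g", correlation$r,
      correlation$bf_plus0)

  sequential <- NULL
  if (!correlation$degenerate && correlation$n >= config$n_start) {
    sequential <- sequential_bf(correlation$data$length,
                                correlation$data$orientation,
                                n_start = config$n_start,
                                bf_high = config$bf_high,
                                bf_low = config$bf_low,
                                kappa = config$kappa)
  }

  result <- list(
    design = design, trials = trials, scores = scores,
    screening = screening, reliability = reliability,
    correlation = correlation, sequential = sequential,
    config_hash = hash
  )
  if (!is.null(out_dir)) {
    write_bundle(result, config, out_dir)
    say("write", "artifacts written to %s", out_dir)
  }
  invisible(result)
}

# config as plain nested list (for hashing and JSON round-trip)
unclass_config <- function(config) {
  out <- unclass(config)
  out$cohort <- unclass(out$cohort)
  out
}

write_bundle <- function(result, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(config = unclass_config(config), config_hash = result$config_hash,
         design = result$design),
    file.path(out_dir, "design.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  readr::write_csv(result$trials, file.path(out_dir, "trials.csv"))
  readr::write_csv(result$scores, file.path(out_dir, "scores.csv"))
  jsonlite::write_json(
    list(config_hash = result$config_hash,
         screening = result$screening, reliability = result$reliability),
    file.path(out_dir, "screening.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  corr <- result$correlation
  seq_part <- if (!is.null(result$sequential)) {
    list(
      n_start = result$sequential$n_start,
      n_stop = result$sequential$n_stop,
      decision = result$sequential$decision,
      trajectory = result$sequential$trajectory
    )
  }
  jsonlite::write_json(
    list(
      config_hash = result$config_hash,
      correlation = list(
        measure = corr$measure, r = corr$r, n = corr$n,
        bf_plus0 = corr$bf_plus0,
        ci_low = corr$ci[["low"]], ci_high = corr$ci[["high"]],
        jeffreys = corr$jeffreys, degenerate = corr$degenerate,
        r_disattenuated = corr$disattenuated$r_disattenuated,
        shared_variance = corr$disattenuated$shared_variance
      ),
      sequential = seq_part
    ),
    file.path(out_dir, "result.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(out_dir)
}

#' Ingest an external trial table
#'
#' Reads a trial-level CSV through the same validation path as simulated
#' data. The documented schema has columns `observer_id`, `task`, `trial`,
#' `true_mean`, `response`; files with other headers are accepted through an
#' explicit column `mapping`. Rows whose response or true mean falls outside
#' the task's probe set are reported with their row numbers.
#'
#' @param path Path to a CSV file (comma-separated, UTF-8, header row,
#'   `.` decimal).
#' @param mapping Optional named character vector mapping schema names to the
#'   file's column names, e.g. `c(observer_id = "subject")`.
#' @return A scored trial tibble (see [score_trials()]).
#' @export
read_trials <- function(path, mapping = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(mapping)) {
    missing_src <- setdiff(unname(mapping), names(raw))
    if (length(missing_src) > 0) {
      stop("mapped column(s) not in file: ",
           paste(missing_src, collapse = ", "), call. = FALSE)
    }
    raw <- dplyr::rename(raw, !!!rlang::set_names(mapping, names(mapping)))
  }
  score_trials(raw)
}
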