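#' Feature value grid
#'
#' The discrete grids from which individual line features are drawn: lengths
#' run from 44 to 116 px in 4 px steps, orientations from 4.5 to 85.5 degrees
#' (clockwise from vertical) in 4.5 degree steps; 19 values each.
#'
#' @param feature `"length"` or `"orientation"`.
#' @return A numeric vector of 19 allowed feature values, with attributes
#'   `feature` and `step`.
#' @export
#' @examples
#' value_grid("length")
value_grid <- function(feature = c("length", "orientation")) {
  feature <- match.arg(feature)
  g <- if (feature == "length") seq(44, 116, by = 4) else seq(4.5, 85.5, by = 4.5)
  structure(g, feature = feature, step = if (feature == "length") 4 else 4.5)
}

#' Probe values for the 5-AFC response screen
#'
#' Each task offers five probe alternatives; these coincide with the five
#' possible true ensemble means of the task, so a response is correct exactly
#' when its error is zero.
#'
#' @param task `"length"` (px) or `"orientation"` (degrees).
#' @return Numeric vector of 5 probe values.
#' @export
probe_set <- function(task = c("length", "orientation")) {
  task <- match.arg(task)
  if (task == "length") c(56, 68, 80, 92, 104) else c(18, 31.5, 45, 58.5, 72)
}

# Factor levels of the two factorial designs. The task-relevant feature takes
# 5 mean levels; the irrelevant feature the middle 3.
design_factors <- function(task) {
  if (task == "length") {
    list(
      mean_length = c(56, 68, 80, 92, 104), sd_length = c(8, 12),
      mean_orientation = c(31.5, 45, 58.5), sd_orientation = c(9, 13.5)
    )
  } else {
    list(
      mean_orientation = c(18, 31.5, 45, 58.5, 72), sd_orientation = c(9, 13.5),
      mean_length = c(68, 80, 92), sd_length = c(8, 12)
    )
  }
}

#' Factorial trial design for one averaging task
#'
#' Fully crosses the task's factor levels (5 relevant means x 2 relevant SDs x
#' 3 irrelevant means x 2 irrelevant SDs x 2 repetitions), giving 120 trial
#' specifications. With a seed the rows are shuffled into a fixed random trial
#' order; the `trial` column always numbers the rows in administration order.
#'
#' @param task `"length"` or `"orientation"`.
#' @param seed Optional integer; shuffles the specs into the trial order.
#' @return A tibble with one row per trial: `task`, `trial`, `mean_length`,
#'   `sd_length`, `mean_orientation`, `sd_orientation`, `repetition`.
#' @export
#' @examples
#' task_design("length")
task_design <- function(task = c("length", "orientation"), seed = NULL) {
  task <- match.arg(task)
  f <- design_factors(task)
  d <- tidyr::expand_grid(
    mean_length = f$mean_length, sd_length = f$sd_length,
    mean_orientation = f$mean_orientation, sd_orientation = f$sd_orientation,
    repetition = 1:2
  )
  if (!is.null(seed)) {
    d <- withr::with_seed(seed, d[sample.int(nrow(d)), ])
  }
  dplyr::mutate(d, task = task, trial = dplyr::row_number(), .before = 1)
}

#' Practice trial design
#'
#' Ten easier warm-up trials: the task-relevant mean is one of the five main
#' probe values, but the relevant SD is reduced to 4 px (length) or 4.5
#' degrees (orientation). Practice ensembles use a fixed layout restricted to
#' grid columns 1, 3 and 5 (see [practice_layout()]).
#'
#' @inheritParams task_design
#' @param seed Integer seed for sampling the factor levels.
#' @return A tibble of 10 trial specifications (same columns as
#'   [task_design()]).
#' @export
practice_design <- function(task = c("length", "orientation"), seed = NULL) {
  task <- match.arg(task)
  f <- design_factors(task)
  draw <- function() {
    if (task == "length") {
      tibble::tibble(
        mean_length = sample(f$mean_length, 10, replace = TRUE),
        sd_length = 4,
        mean_orientation = sample(f$mean_orientation, 10, replace = TRUE),
        sd_orientation = sample(f$sd_orientation, 10, replace = TRUE)
      )
    } else {
      tibble::tibble(
        mean_length = sample(f$mean_length, 10, replace = TRUE),
        sd_length = sample(f$sd_length, 10, replace = TRUE),
        mean_orientation = sample(f$mean_orientation, 10, replace = TRUE),
        sd_orientation = 4.5
      )
    }
  }
  d <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  dplyr::mutate(d, task = task, trial = dplyr::row_number(),
                repetition = 1L, practice = TRUE, .before = 1)
}

#' Spatial layouts for the counterbalanced experiment versions
#'
#' Each experiment version fixes one spatial configuration per task, used
#' unchanged on every trial of that task so line locations are fully
#' predictable. Cells live on a 4-row by 5-column grid with exactly 3 of the
#' 5 cells occupied in each row.
#'
#' @param n_versions Number of counterbalanced versions (default 5).
#' @param seed Integer seed for the constrained sampling.
#' @return A tibble with columns `version`, `task`, `line` (1-12), `row`
#'   (1-4), `col` (1-5).
#' @export
#' @examples
#' build_layouts(5, seed = 1)
build_layouts <- function(n_versions = 5, seed = NULL) {
  stopifnot(n_versions >= 1)
  one <- function(version, task) {
    cols <- unlist(lapply(1:4, function(r) sort(sample(5, 3))))
    tibble::tibble(
      version = version, task = task, line = 1:12,
      row = rep(1:4, each = 3), col = cols
    )
  }
  build <- function() {
    purrr::map_dfr(seq_len(n_versions), function(v) {
      dplyr::bind_rows(one(v, "length"), one(v, "orientation"))
    })
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Fixed layout for practice trials
#'
#' Practice ensembles occupy all 12 cells of grid columns 1, 3 and 5.
#'
#' @return A tibble with columns `line`, `row`, `col`.
#' @export
practice_layout <- function() {
  tibble::tibble(line = 1:12, row = rep(1:4, each = 3), col = rep(c(1, 3, 5), 4))
}

#' Sample grid values with an exact mean and a controlled SD
#'
#' Finds `n` values on a uniform discrete grid whose sample mean equals
#' `target_mean` exactly and whose sample SD (n-1 denominator) is within
#' `sd_tol` of `target_sd`. The search works in integer grid-step units:
#' paired +1/-1 moves preserve the sum (hence the mean) exactly, and a greedy
#' descent on the sum of squared deviations, with random restarts, steers the
#' SD to the closest value the grid parity admits.
#'
#' @param grid Uniformly spaced numeric grid (see [value_grid()]).
#' @param target_mean Required sample mean; `n * target_mean` must be
#'   representable as a sum of grid values.
#' @param target_sd Required sample SD.
#' @param n Number of values (default 12).
#' @param sd_tol Acceptable |SD - target| in feature units (default 0.5).
#' @param max_restarts Random restarts before giving up (default 100).
#' @return Numeric vector of `n` grid values in random order.
#' @export
#' @examples
#' x <- sample_feature_values(value_grid("length"), 80, 12)
#' mean(x); sd(x)
sample_feature_values <- function(grid, target_mean, target_sd, n = 12,
                                  sd_tol = 0.5, max_restarts = 100) {
  step <- attr(grid, "step") %||% diff(grid)[1]
  k_max <- length(grid) - 1L
  S <- (target_mean - grid[1]) / step * n
  if (abs(S - round(S)) > 1e-8) {
    stop("target mean ", target_mean, " is not representable as a mean of ",
         n, " grid values", call. = FALSE)
  }
  S <- as.integer(round(S))
  if (S < 0 || S > n * k_max) {
    stop("target mean ", target_mean, " lies outside the grid", call. = FALSE)
  }
  sd_steps <- target_sd / step
  tol_steps <- sd_tol / step
  target_ss <- (n - 1) * sd_steps^2            # sum of squared deviations

  ssd <- function(k) sum((k - S / n)^2)
  sd_err <- function(k) abs(sqrt(ssd(k) / (n - 1)) - sd_steps)

  # Greedy descent: the move (k[i]+1, k[j]-1) changes the sum of squared
  # deviations by 2 * (k[i] - k[j] + 1); pick the feasible move bringing it
  # closest to target_ss, stop when no move improves.
  descend <- function(k) {
    repeat {
      cur <- ssd(k)
      if (abs(sqrt(cur / (n - 1)) - sd_steps) <= tol_steps) return(k)
      up <- which(k < k_max)
      dn <- which(k > 0L)
      cand <- expand.grid(i = up, j = dn)
      cand <- cand[cand$i != cand$j, , drop = FALSE]
      if (nrow(cand) == 0L) return(k)
      delta <- 2 * (k[cand$i] - k[cand$j] + 1)
      err_new <- abs(cur + delta - target_ss)
      best <- which.min(err_new)
      if (err_new[best] >= abs(cur - target_ss)) return(k)
      k[cand$i[best]] <- k[cand$i[best]] + 1L
      k[cand$j[best]] <- k[cand$j[best]] - 1L
    }
  }

  base <- S %/% n
  rem <- S %% n
  k0 <- rep(as.integer(base), n)
  if (rem > 0) k0[seq_len(rem)] <- k0[seq_len(rem)] + 1L

  best_k <- NULL
  best_err <- Inf
  for (restart in seq_len(max_restarts)) {
    k <- k0
    if (restart > 1) {                         # random feasible perturbation
      for (m in seq_len(3 * n)) {
        i <- sample.int(n, 1); j <- sample.int(n, 1)
        if (i != j && k[i] < k_max && k[j] > 0L) {
          k[i] <- k[i] + 1L; k[j] <- k[j] - 1L
        }
      }
    }
    k <- descend(k)
    e <- sd_err(k)
    if (e < best_err) {
      best_err <- e
      best_k <- k
    }
    if (best_err <= tol_steps) break
  }
  if (best_err > tol_steps) {
    stop("no ensemble with mean ", target_mean, " and SD within ", sd_tol,
         " of ", target_sd, " found in ", max_restarts, " restarts",
         call. = FALSE)
  }
  sample(grid[best_k + 1L])
}

#' Realize one ensemble specification as 12 lines
#'
#' Draws 12 lengths and 12 orientations meeting the spec's mean/SD targets
#' (mean exact, SD within `sd_tol`), shuffles the two feature lists
#' independently so length and orientation are uncorrelated across lines, and
#' pairs them with the layout cells.
#'
#' @param spec A one-row data frame with columns `mean_length`, `sd_length`,
#'   `mean_orientation`, `sd_orientation` (e.g. one row of [task_design()]).
#' @param layout A 12-row tibble with columns `line`, `row`, `col`; defaults
#'   to the first version of [build_layouts()] for the spec's task.
#' @param sd_tol SD tolerance passed to [sample_feature_values()].
#' @param max_restarts Restart budget per feature.
#' @return A 12-row tibble: `line`, `length`, `orientation`, `row`, `col`.
#' @export
sample_ensemble <- function(spec, layout = NULL, sd_tol = 0.5,
                            max_restarts = 100) {
  spec <- as.list(spec)
  if (is.null(layout)) {
    layout <- practice_layout()
  }
  stopifnot(nrow(layout) == 12, !anyDuplicated(layout[c("row", "col")]))
  lens <- sample_feature_values(value_grid("length"), spec$mean_length,
                                spec$sd_length, sd_tol = sd_tol,
                                max_restarts = max_restarts)
  oris <- sample_feature_values(value_grid("orientation"), spec$mean_orientation,
                                spec$sd_orientation, sd_tol = sd_tol,
                                max_restarts = max_restarts)
  tibble::tibble(
    line = 1:12,
    length = lens,
    orientation = oris,
    row = layout$row,
    col = layout$col
  )
}

#' Realize a whole trial design as line-level stimuli
#'
#' Applies [sample_ensemble()] to every trial of a design, reusing one fixed
#' layout for all trials (spatially fully predictable stimuli).
#'
#' @param design A design tibble from [task_design()] or [practice_design()].
#' @param layout A 12-row layout tibble; defaults to [practice_layout()] for
#'   practice designs, otherwise to a layout drawn from `seed`.
#' @param sd_tol,max_restarts Passed to [sample_feature_values()].
#' @param seed Integer seed making the realization reproducible.
#' @return A tibble with 12 rows per trial: design columns plus `line`,
#'   `length`, `orientation`, `row`, `col`.
#' @export
#' @examples
#' d <- realize_design(task_design("length", seed = 1), seed = 1)
realize_design <- function(design, layout = NULL, sd_tol = 0.5,
                           max_restarts = 100, seed = NULL) {
  task <- design$task[1]
  run <- function() {
    if (is.null(layout)) {
      layout <- if ("practice" %in% names(design) && isTRUE(design$practice[1])) {
        practice_layout()
      } else {
        dplyr::select(
          dplyr::filter(build_layouts(1), .data$task == !!task),
          "line", "row", "col"
        )
      }
    }
    purrr::map_dfr(seq_len(nrow(design)), function(i) {
      ens <- sample_ensemble(design[i, ], layout, sd_tol = sd_tol,
                             max_restarts = max_restarts)
      dplyr::bind_cols(design[rep(i, 12), ], ens)
    })
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
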