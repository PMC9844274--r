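#' Tidy a Bayesian task correlation
#'
#' @param x An `ens_cor` object from [correlate_tasks()].
#' @param ... Unused.
#' @return A one-row tibble: `measure`, `estimate`, `n`, `bf_plus0`,
#'   `evidence`, `conf.low`, `conf.high`, and when available
#'   `r_disattenuated`, `shared_variance`.
#' @export
tidy.ens_cor <- function(x, ...) {
  out <- tibble::tibble(
    measure = x$measure,
    estimate = x$r,
    n = x$n,
    bf_plus0 = x$bf_plus0,
    evidence = if (is.na(x$bf_plus0)) NA_character_ else x$jeffreys,
    conf.low = x$ci[["low"]],
    conf.high = x$ci[["high"]]
  )
  if (!is.null(x$disattenuated)) {
    out$r_disattenuated <- x$disattenuated$r_disattenuated
    out$shared_variance <- x$disattenuated$shared_variance
  }
  out
}

#' Glance at a Bayesian task correlation
#'
#' @inheritParams tidy.ens_cor
#' @return A one-row tibble with `n`, `kappa`, `level`, `degenerate`.
#' @export
glance.ens_cor <- function(x, ...) {
  tibble::tibble(n = x$n, kappa = x$kappa, level = x$level,
                 degenerate = x$degenerate)
}

#' Tidy a sequential Bayes factor run
#'
#' @param x An `ens_seq` object from [sequential_bf()].
#' @param ... Unused.
#' @return The look-by-look trajectory: `n`, `r`, `bf`.
#' @export
tidy.ens_seq <- function(x, ...) x$trajectory

#' Glance at a sequential Bayes factor run
#'
#' @inheritParams tidy.ens_seq
#' @return A one-row tibble: `n_start`, `n_stop`, `decision`, `bf_final`.
#' @export
glance.ens_seq <- function(x, ...) {
  tibble::tibble(
    n_start = x$n_start,
    n_stop = x$n_stop,
    decision = x$decision,
    bf_final = x$trajectory$bf[nrow(x$trajectory)]
  )
}

#' Scatterplot of the two task error measures
#'
#' The classic individual-differences picture: one point per participant,
#' length-task measure against orientation-task measure, with a linear fit.
#'
#' @param object An `ens_cor` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ens_cor <- function(object, ...) {
  lab <- if (object$measure == "mean_abs_error") "mean absolute error" else object$measure
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(x = .data$length, y = .data$orientation)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = paste("Length task", lab, "(px)"),
      y = paste("Orientation task", lab, "(deg)"),
      title = if (object$degenerate) {
        "Task correlation (degenerate input)"
      } else {
        sprintf("r = %.2f, BF+0 = %.3g (n = %d)",
                object$r, object$bf_plus0, object$n)
      }
    ) +
    ggplot2::theme_minimal()
  if (!object$degenerate) {
    p <- p + ggplot2::geom_smooth(method = "lm", formula = y ~ x)
  }
  p
}

#' Bayes factor trajectory of a sequential design
#'
#' @param object An `ens_seq` object.
#' @param ... Unused.
#' @return A ggplot object (log-scaled BF axis with the stopping boundaries).
#' @export
autoplot.ens_seq <- function(object, ...) {
  ggplot2::ggplot(object$trajectory, ggplot2::aes(x = .data$n, y = .data$bf)) +
    ggplot2::geom_hline(yintercept = c(object$bf_low, object$bf_high),
                        linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "paired observations", y = "BF+0",
                  title = sprintf("Sequential design: %s at n = %d",
                                  object$decision, object$n_stop)) +
    ggplot2::theme_minimal()
}

#' @export
plot.ens_cor <- function(x, ...) print(autoplot(x, ...))

#' @export
plot.ens_seq <- function(x, ...) print(autoplot(x, ...))
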