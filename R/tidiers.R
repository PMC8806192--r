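# broom-style tidiers and ggplot2 autoplot methods for fitted objects.

#' Tidy a FUCCI calibration
#'
#' @param x A `fucci_calibration`.
#' @param ... Ignored.
#' @return One row per polynomial coefficient (`term`, `estimate`).
#' @method tidy fucci_calibration
#' @export
tidy.fucci_calibration <- function(x, ...) {
  tibble::tibble(term = c("intercept", "t", "t^2", "t^3"),
                 estimate = x$coefficients)
}

#' @rdname tidy.fucci_calibration
#' @method glance fucci_calibration
#' @export
glance.fucci_calibration <- function(x, ...) {
  tibble::tibble(t_min = x$valid_time_range[1],
                 t_max = x$valid_time_range[2],
                 early_s_mean = x$early_s_mean,
                 n_traces = x$n_traces,
                 median_timing_sd = if (is.null(x$timing_sd_table)) NA_real_
                 else median(x$timing_sd_table$timing_sd))
}

#' Tidy a decay fit
#'
#' @param x A `decay_fit`.
#' @param ... Ignored.
#' @return A one-row tibble with the kinetic parameters, onset time, SSE,
#'   half-life, and convergence flags.
#' @method tidy decay_fit
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(gene_id = x$gene_id, m0 = x$m0, mu = x$mu, gamma = x$gamma,
                 t_onset = x$t_onset, sse = x$sse, half_life = x$half_life,
                 steady_state = x$steady_state, converged = x$converged,
                 decaying = x$decaying)
}

#' @rdname tidy.decay_fit
#' @method glance decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(sse = x$sse, n_cells = x$n_cells, converged = x$converged,
                 decaying = x$decaying)
}

#' Plot a FUCCI calibration curve
#'
#' Mean normalized trace (points) with the fitted third-order polynomial
#' (line) and, when available, a ribbon of +/- 1 timing SD mapped back to
#' intensity.
#'
#' @param object A `fucci_calibration`.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot fucci_calibration
#' @export
autoplot.fucci_calibration <- function(object, ...) {
  grid <- seq(object$valid_time_range[1], object$valid_time_range[2],
              length.out = 200)
  fitted <- tibble::tibble(t_min = grid,
                           normalized_g1 = predict(object, grid))
  ggplot2::ggplot(object$mean_trace,
                  ggplot2::aes(x = .data$t_min, y = .data$normalized_g1)) +
    ggplot2::geom_point(colour = "firebrick", size = 1) +
    ggplot2::geom_line(data = fitted) +
    ggplot2::labs(x = "time since metaphase (min)",
                  y = "FUCCI-G1 intensity (early-S normalized)",
                  title = "FUCCI-G1 calibration curve") +
    ggplot2::theme_minimal()
}

#' Plot a single-gene decay fit
#'
#' Per-cell expression against cell-cycle time with the fitted two-phase
#' decay model overlaid and the onset time marked.
#'
#' @param object A `decay_fit`.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot decay_fit
#' @export
autoplot.decay_fit <- function(object, ...) {
  grid <- seq(min(object$data$t), max(object$data$t), length.out = 400)
  curve <- tibble::tibble(
    t = grid,
    expression = decay_model(grid, object$m0, object$mu, object$gamma,
                             object$t_onset))
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$t, y = .data$expression)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.7) +
    ggplot2::geom_line(data = curve, colour = "firebrick", linewidth = 0.9) +
    ggplot2::geom_vline(xintercept = object$t_onset, linetype = "dashed") +
    ggplot2::labs(x = "time since metaphase (min)",
                  y = "normalized expression",
                  title = object$gene_id %||% "decay fit",
                  subtitle = sprintf(
                    "t_onset = %g min, half-life = %.1f min",
                    object$t_onset, object$half_life)) +
    ggplot2::theme_minimal()
}

#' Onset-time histogram of decay fits
#'
#' @param fits Tibble from [fit_decay_genes()] (converged decaying genes are
#'   shown).
#' @param binwidth Histogram bin width in minutes (default one grid step,
#'   10 min).
#' @return A ggplot.
#' @export
plot_onset_histogram <- function(fits, binwidth = 10) {
  use <- fits[fits$converged & fits$decaying, , drop = FALSE]
  ggplot2::ggplot(use, ggplot2::aes(x = .data$t_onset)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = -binwidth / 2,
                            fill = "grey30") +
    ggplot2::labs(x = "onset time (min since metaphase)", y = "genes",
                  title = "Decay onset times") +
    ggplot2::theme_minimal()
}

#' Wave-call overview plot
#'
#' Crossing time (first normalized-derivative <= threshold) per gene,
#' coloured by wave group.
#'
#' @param waves Tibble from [call_waves()].
#' @return A ggplot.
#' @export
plot_wave_calls <- function(waves) {
  use <- waves[waves$wave_group != "degenerate", , drop = FALSE]
  ggplot2::ggplot(use, ggplot2::aes(x = .data$t_cross,
                                    fill = .data$wave_group)) +
    ggplot2::geom_histogram(binwidth = 10, boundary = 0,
                            position = "identity", alpha = 0.7) +
    ggplot2::labs(x = "-0.95 crossing time (min)", y = "genes",
                  fill = "wave", title = "mRNA decline waves") +
    ggplot2::theme_minimal()
}
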