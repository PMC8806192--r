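# FUCCI calibration: convert FUCCI-G1 reporter fluorescence into absolute
# minutes since metaphase. The mean of the aligned live-cell traces is fit to
# a third-order polynomial after normalizing intensities to the early-S-phase
# mean; per-cell times come from numerically inverting that polynomial.

#' Correct G1-into-G2 channel crosstalk
#'
#' The FUCCI-G1 marker is also excited by the laser used for the G2 channel;
#' a fixed fraction (31% for this reporter line) of the G1 intensity is
#' subtracted from the raw G2 intensity. The result may be negative (noise);
#' the caller decides whether to floor it.
#'
#' @param g1 G1-channel intensity (vector).
#' @param g2_raw Raw G2-channel intensity (vector).
#' @param fraction Crosstalk fraction in \[0, 1\]; default 0.31.
#' @return Corrected G2 intensity, `g2_raw - fraction * g1`.
#' @export
#' @examples
#' correct_crosstalk(100, 50)  # 19
correct_crosstalk <- function(g1, g2_raw, fraction = 0.31) {
  if (length(fraction) != 1L || is.na(fraction) || fraction < 0 || fraction > 1)
    stop("`fraction` must be a single value in [0, 1]", call. = FALSE)
  g2_raw - fraction * g1
}

#' Gate early-S-phase cells
#'
#' Early-S cells are those whose (crosstalk-corrected) G2 intensity lies
#' between 2.5% and 10% of the G2 intensity range and whose G1 intensity
#' exceeds 2.5% of the G1 range. Their mean G1 intensity is the normalization
#' factor that makes microscopy and FACS intensities comparable.
#'
#' @param records Data frame with at least `g1` and `g2` intensity columns
#'   (names configurable); `g2` must already be crosstalk-corrected.
#' @param g1_col,g2_col Column names.
#' @param g2_bounds Lower/upper gate bounds as fractions of the G2 range.
#' @param g1_lower Lower G1 gate bound as a fraction of the G1 range.
#' @param range_method `"minmax"` (literal max - min) or `"robust"`
#'   (0.5-99.5 percentile range, guarding against FACS outliers).
#' @param min_cells Minimum acceptable gate size.
#' @return A list with `cells` (the gated subset), `mean_g1`, `n`, and the
#'   intensity thresholds used.
#' @export
gate_early_s <- function(records, g1_col = "g1", g2_col = "g2",
                         g2_bounds = c(0.025, 0.10), g1_lower = 0.025,
                         range_method = c("minmax", "robust"),
                         min_cells = 5L) {
  range_method <- match.arg(range_method)
  g1 <- records[[g1_col]]
  g2 <- records[[g2_col]]
  if (is.null(g1) || is.null(g2))
    stop("`records` must contain columns `", g1_col, "` and `", g2_col, "`",
         call. = FALSE)
  rng <- function(x) {
    if (range_method == "minmax") range(x)
    else quantile(x, c(0.005, 0.995), names = FALSE)
  }
  r1 <- rng(g1); r2 <- rng(g2)
  # thresholds are fractions of the range magnitude (max - min), applied as
  # absolute intensities
  lo2 <- g2_bounds[1] * diff(r2)
  hi2 <- g2_bounds[2] * diff(r2)
  lo1 <- g1_lower * diff(r1)
  member <- g2 >= lo2 & g2 <= hi2 & g1 >= lo1
  if (!any(member))
    stop("early-S gate is empty: no cell has G2 in [",
         signif(lo2, 4), ", ", signif(hi2, 4), "] and G1 >= ",
         signif(lo1, 4), call. = FALSE)
  if (sum(member) < min_cells)
    warning("early-S gate holds only ", sum(member), " cells (< ", min_cells,
            ")", call. = FALSE)
  list(cells = records[member, , drop = FALSE],
       mean_g1 = mean(g1[member]), n = sum(member),
       thresholds = c(g2_low = lo2, g2_high = hi2, g1_low = lo1))
}

# Align traces at metaphase, correct crosstalk, and clip each trace at the
# end of G1 (first time the corrected G2 signal exceeds `clip_frac` of the
# corrected-G2 range). Returns the clipped long table.
clip_traces_at_g1_end <- function(traces, crosstalk_fraction = 0.31,
                                  clip_frac = 0.05) {
  stopifnot(all(c("cell_id", "t_min", "g1", "g2_raw") %in% names(traces)))
  traces <- dplyr::mutate(traces,
    g2_corrected = correct_crosstalk(.data$g1, .data$g2_raw,
                                     crosstalk_fraction))
  rng <- range(traces$g2_corrected)
  if (diff(rng) == 0) return(traces)  # flat G2 channel: nothing to clip
  thr <- rng[1] + clip_frac * diff(rng)
  traces |>
    dplyr::arrange(.data$cell_id, .data$t_min) |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::mutate(.rise = cumsum(.data$g2_corrected >= thr) > 0) |>
    dplyr::filter(!.data$.rise) |>
    dplyr::select(-".rise") |>
    dplyr::ungroup()
}

#' Fit the mean FUCCI-G1 trace to a third-order polynomial
#'
#' Traces (aligned at the metaphase-to-anaphase transition) are clipped at
#' the end of G1 where the crosstalk-corrected G2 signal starts to rise, the
#' per-time-point mean G1 intensity is normalized to the early-S mean, and a
#' least-squares order-3 polynomial of normalized intensity versus time is
#' fit. The fit must be strictly increasing on the valid range.
#'
#' @param traces Long tibble of traces: `cell_id`, `t_min`, `g1`, `g2_raw`.
#' @param early_s_mean Mean G1 intensity of early-S cells (microscopy). If
#'   `NULL`, the mean of each trace's last retained (end-of-G1) G1 value is
#'   used: FUCCI-G1 stays high into early S, so the G1-end level is the
#'   early-S level.
#' @param crosstalk_fraction G1-into-G2 crosstalk fraction for the clipping
#'   step.
#' @param clip_frac End-of-G1 clipping threshold as a fraction of the
#'   corrected G2 range.
#' @param min_coverage Fraction of traces that must still be unclipped for a
#'   time point to enter the mean trace (sets the upper end of the valid
#'   range).
#' @return A `fucci_calibration` object: polynomial `coefficients`
#'   (intercept first), `valid_time_range`, `early_s_mean`, and (after
#'   [timing_sd()]) a `timing_sd_table`.
#' @export
fit_mean_trace_polynomial <- function(traces, early_s_mean = NULL,
                                      crosstalk_fraction = 0.31,
                                      clip_frac = 0.05,
                                      min_coverage = 0.5) {
  clipped <- clip_traces_at_g1_end(traces, crosstalk_fraction, clip_frac)
  n_traces <- dplyr::n_distinct(clipped$cell_id)
  if (is.null(early_s_mean)) {
    ends <- clipped |>
      dplyr::group_by(.data$cell_id) |>
      dplyr::slice_max(.data$t_min, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
    early_s_mean <- mean(ends$g1)
  }
  if (!is.finite(early_s_mean) || early_s_mean <= 0)
    stop("`early_s_mean` must be a positive intensity", call. = FALSE)

  mean_trace <- clipped |>
    dplyr::group_by(.data$t_min) |>
    dplyr::summarise(mean_g1 = mean(.data$g1), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::filter(.data$n >= min_coverage * n_traces)
  if (nrow(mean_trace) < 4L)
    stop("need at least 4 distinct time points to fit an order-3 polynomial",
         call. = FALSE)

  y <- mean_trace$mean_g1 / early_s_mean
  t <- mean_trace$t_min
  fit <- lm(y ~ t + I(t^2) + I(t^3))
  cf <- unname(coef(fit))
  rng <- range(t)
  grid <- seq(rng[1], rng[2], length.out = 512)
  deriv <- cf[2] + 2 * cf[3] * grid + 3 * cf[4] * grid^2
  if (any(deriv <= 0))
    stop("fitted polynomial is not strictly increasing on [",
         rng[1], ", ", rng[2], "] min; reduce the valid time range ",
         "(e.g. clip traces earlier)", call. = FALSE)
  structure(list(coefficients = cf, valid_time_range = rng,
                 early_s_mean = early_s_mean, timing_sd_table = NULL,
                 n_traces = n_traces,
                 mean_trace = tibble::tibble(t_min = t, normalized_g1 = y)),
            class = "fucci_calibration")
}

#' @export
print.fucci_calibration <- function(x, ...) {
  cf <- signif(x$coefficients, 4)
  cat("<fucci_calibration>\n")
  cat(sprintf("  p(t) = %g + %g t + %g t^2 + %g t^3\n",
              cf[1], cf[2], cf[3], cf[4]))
  cat("  valid range:", x$valid_time_range[1], "-", x$valid_time_range[2],
      "min | early-S mean intensity:", signif(x$early_s_mean, 5), "\n")
  if (!is.null(x$timing_sd_table))
    cat("  timing SD: median", signif(median(x$timing_sd_table$timing_sd), 3),
        "min over", nrow(x$timing_sd_table), "time points\n")
  invisible(x)
}

# Evaluate the calibration polynomial (normalized intensity scale).
#' @export
predict.fucci_calibration <- function(object, t, ...) {
  cf <- object$coefficients
  cf[1] + cf[2] * t + cf[3] * t^2 + cf[4] * t^3
}

#' Invert the calibration curve: intensity to minutes since metaphase
#'
#' Finds the unique root of `p(t) = normalized_g1` on the valid time range
#' by bracketed root finding. Intensities below `p(t_min)` clamp to `t_min`
#' (`clamped_low`), above `p(t_max)` to `t_max` (`clamped_high`); times
#' beyond the confidence horizon are flagged `low_confidence` (timing
#' accuracy degrades late in G1 as cell-to-cell FUCCI heterogeneity grows).
#'
#' @param curve A `fucci_calibration` object.
#' @param normalized_g1 Intensities on the early-S-normalized scale (vector).
#' @param confidence_horizon Minutes beyond which inferred times are flagged
#'   `low_confidence` (default 300, ~5 hr).
#' @param tol Root-finding tolerance in minutes.
#' @return A tibble with `normalized_g1`, `cell_cycle_time`, `time_flag`
#'   (`ok`, `clamped_low`, `clamped_high`, `low_confidence`).
#' @export
invert_time <- function(curve, normalized_g1, confidence_horizon = 300,
                        tol = 1e-6) {
  stopifnot(inherits(curve, "fucci_calibration"))
  rng <- curve$valid_time_range
  p_lo <- predict(curve, rng[1])
  p_hi <- predict(curve, rng[2])
  one <- function(v) {
    if (is.na(v)) return(c(NA_real_, NA))
    if (v <= p_lo) return(c(rng[1], 1))  # clamped_low
    if (v >= p_hi) return(c(rng[2], 2))  # clamped_high
    root <- uniroot(function(t) predict(curve, t) - v, interval = rng,
                    tol = tol)$root
    c(root, 0)
  }
  res <- vapply(normalized_g1, one, numeric(2))
  time <- res[1, ]
  flag <- dplyr::case_when(
    is.na(time) ~ NA_character_,
    res[2, ] == 1 ~ "clamped_low",
    res[2, ] == 2 ~ "clamped_high",
    time > confidence_horizon ~ "low_confidence",
    TRUE ~ "ok")
  tibble::tibble(normalized_g1 = normalized_g1, cell_cycle_time = time,
                 time_flag = flag)
}

#' Timing uncertainty of the calibration
#'
#' At each trace time point, the mean and SD of the (early-S-normalized) G1
#' intensities across traces are mapped through [invert_time()]; the SD of
#' FUCCI-G1 timing is the average absolute time difference of the +1 SD and
#' -1 SD intensities from the mean-intensity time. Intensities outside the
#' invertible range are clamped and the time point flagged.
#'
#' @param traces Long trace tibble (as for [fit_mean_trace_polynomial()]).
#' @param curve A fitted `fucci_calibration`.
#' @inheritParams fit_mean_trace_polynomial
#' @return The `curve` with its `timing_sd_table` filled: a tibble with
#'   `t_min`, `mean_intensity`, `sd_intensity`, `timing_sd`, `clamped`.
#' @export
timing_sd <- function(traces, curve, crosstalk_fraction = 0.31,
                      clip_frac = 0.05, min_coverage = 0.5) {
  stopifnot(inherits(curve, "fucci_calibration"))
  clipped <- clip_traces_at_g1_end(traces, crosstalk_fraction, clip_frac)
  n_traces <- dplyr::n_distinct(clipped$cell_id)
  if (n_traces < 2L) stop("need at least 2 traces", call. = FALSE)
  stats <- clipped |>
    dplyr::group_by(.data$t_min) |>
    dplyr::summarise(mean_intensity = mean(.data$g1),
                     sd_intensity = sd(.data$g1), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::filter(.data$n >= min_coverage * n_traces,
                  .data$t_min >= curve$valid_time_range[1],
                  .data$t_min <= curve$valid_time_range[2])
  esm <- curve$early_s_mean
  t0 <- invert_time(curve, stats$mean_intensity / esm)
  tp <- invert_time(curve, (stats$mean_intensity + stats$sd_intensity) / esm)
  tm <- invert_time(curve, (stats$mean_intensity - stats$sd_intensity) / esm)
  tbl <- tibble::tibble(
    t_min = stats$t_min,
    mean_intensity = stats$mean_intensity,
    sd_intensity = stats$sd_intensity,
    timing_sd = (abs(tp$cell_cycle_time - t0$cell_cycle_time) +
                 abs(tm$cell_cycle_time - t0$cell_cycle_time)) / 2,
    clamped = tp$time_flag %in% c("clamped_low", "clamped_high") |
      tm$time_flag %in% c("clamped_low", "clamped_high"))
  curve$timing_sd_table <- tbl
  curve
}

#' Fit a full FUCCI calibration from traces
#'
#' Convenience wrapper: [fit_mean_trace_polynomial()] followed by
#' [timing_sd()].
#'
#' @inheritParams fit_mean_trace_polynomial
#' @return A `fucci_calibration` with its timing-SD table.
#' @export
fit_fucci_calibration <- function(traces, early_s_mean = NULL,
                                  crosstalk_fraction = 0.31,
                                  clip_frac = 0.05, min_coverage = 0.5) {
  curve <- fit_mean_trace_polynomial(traces, early_s_mean,
                                     crosstalk_fraction, clip_frac,
                                     min_coverage)
  timing_sd(traces, curve, crosstalk_fraction, clip_frac, min_coverage)
}

#' Assign cell-cycle times to FACS-sorted cells
#'
#' Corrects channel crosstalk, computes (or takes) the FACS early-S mean G1
#' intensity via [gate_early_s()] on the same snapshot, normalizes each
#' cell's G1 intensity to it, and inverts the calibration polynomial for
#' G1-gated cells. G2/M (and any other non-G1) cells keep their record but
#' get no G1 time.
#'
#' @param records FACS tibble: `cell_id`, `plate_id`, `g1_raw`, `g2_raw`,
#'   `gate_label` (`"G1"` rows are timed).
#' @param curve A fitted `fucci_calibration`.
#' @param crosstalk_fraction Crosstalk fraction for the G2 correction.
#' @param early_s_mean FACS early-S mean G1 intensity; computed from the
#'   snapshot via [gate_early_s()] when `NULL`.
#' @param confidence_horizon Passed to [invert_time()].
#' @param ... Passed to [gate_early_s()].
#' @return `records` with added `fucci_g2_corrected`, `normalized_g1`,
#'   `cell_cycle_time`, `time_flag`.
#' @export
assign_times <- function(records, curve, crosstalk_fraction = 0.31,
                         early_s_mean = NULL, confidence_horizon = 300, ...) {
  stopifnot(inherits(curve, "fucci_calibration"),
            all(c("cell_id", "g1_raw", "g2_raw", "gate_label") %in%
                  names(records)))
  records <- dplyr::mutate(records,
    fucci_g2_corrected = correct_crosstalk(.data$g1_raw, .data$g2_raw,
                                           crosstalk_fraction))
  if (is.null(early_s_mean)) {
    gate <- gate_early_s(records, g1_col = "g1_raw",
                         g2_col = "fucci_g2_corrected", ...)
    early_s_mean <- gate$mean_g1
  }
  if (!is.finite(early_s_mean) || early_s_mean <= 0)
    stop("missing or non-positive early-S mean intensity", call. = FALSE)
  records <- dplyr::mutate(records,
    normalized_g1 = .data$g1_raw / early_s_mean)
  is_g1 <- records$gate_label == "G1"
  inv <- invert_time(curve, records$normalized_g1[is_g1],
                     confidence_horizon = confidence_horizon)
  records$cell_cycle_time <- NA_real_
  records$time_flag <- NA_character_
  records$cell_cycle_time[is_g1] <- inv$cell_cycle_time
  records$time_flag[is_g1] <- inv$time_flag
  attr(records, "early_s_mean") <- early_s_mean
  records
}
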