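# Wave detection: smoothing-spline fit of expression vs cell-cycle time,
# derivative-based timing of the steepest decline, and classification into
# the immediate (mitotic-exit) or delayed (early-G1) decay wave.

#' Fit a smoothing spline to a gene's expression profile
#'
#' Penalized cubic smoothing spline of size-factor-normalized expression
#' against cell-cycle time, with the smoothing parameter chosen by
#' generalized cross-validation by default.
#'
#' @param times Per-cell cell-cycle times (min); G2/M cells enter at their
#'   nominal pre-metaphase time so the mitotic-exit decline is anchored on
#'   both sides.
#' @param expression Per-cell normalized expression.
#' @param spar Optional smoothing parameter override (passed to
#'   [stats::smooth.spline()]).
#' @param min_cells,min_span Minimum number of cells and minimum spanned
#'   time (min).
#' @return A `smooth.spline` object.
#' @export
fit_expression_spline <- function(times, expression, spar = NULL,
                                  min_cells = 30L, min_span = 120) {
  ok <- is.finite(times) & is.finite(expression)
  times <- times[ok]; expression <- expression[ok]
  if (length(times) < min_cells)
    stop("need at least ", min_cells, " cells", call. = FALSE)
  if (diff(range(times)) < min_span)
    stop("cells must span at least ", min_span, " min", call. = FALSE)
  if (sd(expression) == 0)
    stop("all-identical expression: degenerate profile", call. = FALSE)
  if (is.null(spar)) {
    smooth.spline(times, expression, cv = FALSE)  # GCV
  } else {
    smooth.spline(times, expression, spar = spar)
  }
}

#' Derivative profile of a fitted expression spline
#'
#' Evaluates the first derivative on a grid and normalizes it to its minimum
#' value, so the steepest decline equals -1 exactly.
#'
#' @param spline_fit A `smooth.spline` from [fit_expression_spline()].
#' @param grid Evaluation times (min), typically 1-min resolution.
#' @return A tibble with `t`, `value`, `derivative`, `normalized_derivative`,
#'   or `NULL` with a warning if the derivative is nowhere negative
#'   (gene not declining).
#' @export
slope_profile <- function(spline_fit, grid) {
  stopifnot(inherits(spline_fit, "smooth.spline"))
  val <- predict(spline_fit, grid)$y
  der <- predict(spline_fit, grid, deriv = 1)$y
  dmin <- min(der)
  if (dmin >= 0) return(NULL)
  tibble::tibble(t = grid, value = val, derivative = der,
                 normalized_derivative = der / abs(dmin))
}

#' Classify a gene into the immediate or delayed decline wave
#'
#' `t_max_decline` is the grid time of the most negative derivative;
#' `t_cross` is the first grid time at which the normalized derivative is at
#' most `threshold` (default -0.95, where -1 is the normalized minimum).
#' In `"window"` mode (default) the gene is `immediate` if `t_cross` falls
#' at or before `boundary` minutes, else `delayed`; in `"strict"` mode only
#' a crossing at the very first grid point counts as immediate.
#'
#' @param profile Tibble from [slope_profile()] (or `NULL` for a
#'   non-declining gene).
#' @param threshold Normalized-derivative crossing threshold (default -0.95).
#' @param mode `"window"` or `"strict"`.
#' @param boundary Window boundary (min) separating the mitotic-exit and
#'   early-G1 onset modes; default 45 (midpoint of the ~10 and ~80 min
#'   modes).
#' @return A one-row tibble: `t_max_decline`, `t_cross`, `wave_group`
#'   (`immediate`, `delayed`, or `degenerate`).
#' @export
classify_wave <- function(profile, threshold = -0.95,
                          mode = c("window", "strict"), boundary = 45) {
  mode <- match.arg(mode)
  if (is.null(profile))
    return(tibble::tibble(t_max_decline = NA_real_, t_cross = NA_real_,
                          wave_group = "degenerate"))
  nd <- profile$normalized_derivative
  t_max <- profile$t[which.min(nd)]
  t_cross <- profile$t[which(nd <= threshold)[1]]
  immediate <- if (mode == "strict") t_cross == profile$t[1]
               else t_cross <= boundary
  tibble::tibble(t_max_decline = t_max, t_cross = t_cross,
                 wave_group = if (immediate) "immediate" else "delayed")
}

#' Call decline waves for a set of genes
#'
#' Runs [fit_expression_spline()], [slope_profile()], and [classify_wave()]
#' per gene over a common 1-min (configurable) evaluation grid from the
#' earliest assigned time to 540 min.
#'
#' @param x A [counts_matrix] with size factors.
#' @param times Named per-cell times (min), including G2/M cells at their
#'   nominal pre-metaphase time; cells with `NA` are dropped.
#' @param genes Gene ids to analyse (typically the downregulated set).
#' @param grid_step Grid resolution (min).
#' @param grid_end Grid end (min).
#' @param spar,threshold,mode,boundary Passed to the per-gene functions.
#' @return A tibble with `gene_id`, `t_max_decline`, `t_cross`,
#'   `wave_group`.
#' @export
call_waves <- function(x, times, genes, grid_step = 1, grid_end = 540,
                       spar = NULL, threshold = -0.95,
                       mode = c("window", "strict"), boundary = 45) {
  stopifnot(inherits(x, "counts_matrix"))
  mode <- match.arg(mode)
  times <- times[intersect(names(times), colnames(x$counts))]
  times <- times[is.finite(times)]
  expr <- normalized_counts(x)[genes, names(times), drop = FALSE]
  grid <- seq(min(times), grid_end, by = grid_step)
  one <- function(i) {
    row <- tryCatch({
      sfit <- fit_expression_spline(times, expr[i, ], spar = spar)
      classify_wave(slope_profile(sfit, grid), threshold = threshold,
                    mode = mode, boundary = boundary)
    }, error = function(e)
      tibble::tibble(t_max_decline = NA_real_, t_cross = NA_real_,
                     wave_group = "degenerate"))
    row
  }
  dplyr::bind_cols(tibble::tibble(gene_id = genes),
                   purrr::map_dfr(seq_along(genes), one))
}
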