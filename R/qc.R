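# SORT-seq quality control: UMI bounds on cells, per-cell recovery
# normalization, and the plate-wise gene-detection filter.

#' Filter cells by total UMI count
#'
#' Removes low-quality cells and doublets: cells with fewer than `lower` or
#' more than `upper` total UMIs are dropped. Bounds are inclusive ("less
#' than" / "more than" exclude only strict violations), so totals of exactly
#' 5900 or 111,000 are kept. The upper default reads the European-style
#' "111.000" as one hundred eleven thousand.
#'
#' @param x A [counts_matrix].
#' @param lower,upper Inclusive UMI-total bounds (defaults 5900 and 111000).
#' @return The filtered `counts_matrix`; `qc_summary()` on it reports kept
#'   and removed cell counts by reason.
#' @export
#' @examples
#' m <- matrix(c(10L, 20L), 2, 2, dimnames = list(c("a", "b"), c("c1", "c2")))
#' filter_cells_by_umi(counts_matrix(m, c("p1", "p1")), lower = 0)
filter_cells_by_umi <- function(x, lower = 5900, upper = 111000) {
  stopifnot(inherits(x, "counts_matrix"))
  if (lower > upper) stop("`lower` must be <= `upper`", call. = FALSE)
  totals <- umi_totals(x)
  low <- totals < lower
  high <- totals > upper
  keep <- !low & !high
  out <- x[, keep]
  attr(out, "qc_summary") <- list(
    n_input = length(totals), n_kept = sum(keep),
    n_removed_low = sum(low), n_removed_high = sum(high),
    lower = lower, upper = upper,
    removed_cells = names(totals)[!keep])
  out
}

#' QC summary of a filtered counts matrix
#'
#' @param x A `counts_matrix` returned by [filter_cells_by_umi()].
#' @return A list with input/kept/removed cell counts, or `NULL`.
#' @export
qc_summary <- function(x) attr(x, "qc_summary")

#' Compute per-cell size factors
#'
#' Normalizes for differences in per-cell mRNA recovery (capture
#' efficiency). This also absorbs the division-driven 2-fold mRNA-content
#' difference between G2/M and G1 cells. Two schemes:
#' * `"libsize"` (default): size factor = total UMIs / geometric mean of
#'   totals;
#' * `"median_ratio"`: median across genes of the ratio to a
#'   geometric-mean reference cell (computed over genes detected in every
#'   cell).
#'
#' Either way factors are rescaled so their log mean is 0.
#'
#' @param x A [counts_matrix] (QC-passed).
#' @param method `"libsize"` or `"median_ratio"`.
#' @return The `counts_matrix` with `size_factors` set.
#' @export
compute_size_factors <- function(x, method = c("libsize", "median_ratio")) {
  stopifnot(inherits(x, "counts_matrix"))
  method <- match.arg(method)
  totals <- umi_totals(x)
  if (any(totals == 0))
    stop("cells with zero total UMIs: ",
         paste(head(names(totals)[totals == 0], 5), collapse = ", "),
         call. = FALSE)
  if (method == "libsize") {
    sf <- totals / exp(mean(log(totals)))
  } else {
    m <- umi_counts(x)
    universal <- rowSums(m > 0) == ncol(m)
    if (sum(universal) < 10)
      stop("too few genes detected in every cell for median-of-ratios; ",
           "use method = \"libsize\"", call. = FALSE)
    logm <- log(m[universal, , drop = FALSE])
    ref <- rowMeans(logm)
    sf <- apply(exp(logm - ref), 2, median)
    sf <- sf / exp(mean(log(sf)))
  }
  x$size_factors <- setNames(as.numeric(sf), colnames(x$counts))
  x
}

#' Plate-wise gene-detection filter
#'
#' Keeps genes whose mean raw count over G2/M cells is at least `min_mean`
#' in every plate. Averaging over G2/M cells avoids biasing against genes
#' downregulated in G1.
#'
#' @param x A [counts_matrix].
#' @param g2m_cells Cell ids of G2/M cells (must cover every plate).
#' @param min_mean Minimum per-plate mean raw count (default 2).
#' @return Character vector of retained gene ids, with the per-plate mean
#'   matrix as attribute `plate_means`.
#' @export
filter_detected_genes <- function(x, g2m_cells, min_mean = 2) {
  stopifnot(inherits(x, "counts_matrix"))
  g2m_cells <- intersect(g2m_cells, colnames(x$counts))
  if (length(g2m_cells) == 0) stop("no G2/M cells in matrix", call. = FALSE)
  plates <- sort(unique(x$plate))
  g2m_plate <- x$plate[g2m_cells]
  missing <- setdiff(plates, unique(g2m_plate))
  if (length(missing) > 0)
    stop("plate(s) without G2/M cells: ", paste(missing, collapse = ", "),
         call. = FALSE)
  m <- umi_counts(x)[, g2m_cells, drop = FALSE]
  plate_means <- vapply(plates, function(p)
    rowMeans(m[, g2m_plate == p, drop = FALSE]), numeric(nrow(m)))
  keep <- rowSums(plate_means >= min_mean) == length(plates)
  out <- rownames(m)[keep]
  attr(out, "plate_means") <- plate_means
  out
}
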