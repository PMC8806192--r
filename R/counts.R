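# A light container for genes x cells UMI counts with per-cell plate labels
# and size factors, plus MatrixMarket / wide-TSV I/O.

#' Construct a counts matrix
#'
#' @param counts Genes x cells matrix (base or `Matrix`) of non-negative
#'   integer UMI counts with gene/cell dimnames.
#' @param plate Per-cell plate labels, named by cell id (or unnamed, in
#'   column order).
#' @param size_factors Optional positive per-cell size factors (see
#'   [compute_size_factors()]).
#' @return A `counts_matrix` object.
#' @export
counts_matrix <- function(counts, plate, size_factors = NULL) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` needs gene rownames and cell colnames", call. = FALSE)
  vals <- if (inherits(counts, "Matrix")) counts@x else counts
  if (any(vals < 0) || any(vals != round(vals)))
    stop("`counts` must be non-negative integers", call. = FALSE)
  if (length(plate) != ncol(counts))
    stop("`plate` must have one label per cell", call. = FALSE)
  if (is.null(names(plate))) names(plate) <- colnames(counts)
  plate <- plate[colnames(counts)]
  if (anyNA(plate)) stop("plate labels missing for some cells", call. = FALSE)
  if (!is.null(size_factors)) {
    if (length(size_factors) != ncol(counts) || any(size_factors <= 0))
      stop("`size_factors` must be positive, one per cell", call. = FALSE)
    if (is.null(names(size_factors)))
      names(size_factors) <- colnames(counts)
    size_factors <- size_factors[colnames(counts)]
  }
  structure(list(counts = counts, plate = plate,
                 size_factors = size_factors),
            class = "counts_matrix")
}

#' @export
dim.counts_matrix <- function(x) dim(x$counts)

#' @export
dimnames.counts_matrix <- function(x) dimnames(x$counts)

#' @export
print.counts_matrix <- function(x, ...) {
  cat("<counts_matrix> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " cells (", length(unique(x$plate)), " plates)\n", sep = "")
  cat("  total UMIs:", sum(x$counts),
      if (is.null(x$size_factors)) "| size factors: not computed"
      else "| size factors: computed", "\n")
  invisible(x)
}

#' Subset a counts matrix
#'
#' @param x A `counts_matrix`.
#' @param i,j Gene / cell indices (names, integers, or logicals).
#' @param ... Ignored.
#' @return A `counts_matrix`.
#' @export
`[.counts_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  counts_matrix(x$counts[i, j, drop = FALSE],
                plate = x$plate[j],
                size_factors = if (!is.null(x$size_factors))
                  x$size_factors[j])
}

#' Extract raw or normalized counts
#'
#' `umi_counts()` returns the raw matrix; `normalized_counts()` divides each
#' cell by its size factor (zeroes and within-cell ranks are preserved).
#'
#' @param x A `counts_matrix`.
#' @return A genes x cells matrix.
#' @export
umi_counts <- function(x) {
  stopifnot(inherits(x, "counts_matrix"))
  as.matrix(x$counts)
}

#' @rdname umi_counts
#' @export
normalized_counts <- function(x) {
  stopifnot(inherits(x, "counts_matrix"))
  if (is.null(x$size_factors))
    stop("size factors not computed; run compute_size_factors() first",
         call. = FALSE)
  sweep(as.matrix(x$counts), 2, x$size_factors, `/`)
}

#' Per-cell UMI totals
#'
#' @param x A `counts_matrix`.
#' @return Named numeric vector of column sums.
#' @export
umi_totals <- function(x) {
  stopifnot(inherits(x, "counts_matrix"))
  Matrix::colSums(x$counts)
}

#' Write / read counts as MatrixMarket with TSV sidecars
#'
#' `write_counts_mtx()` writes `matrix.mtx` (genes x cells, sparse),
#' `genes.tsv` (gene ids) and `cells.tsv` (cell id, plate, size factor).
#' `read_counts_mtx()` reads them back.
#'
#' @param x A `counts_matrix`.
#' @param dir Directory (created if needed).
#' @return The directory (invisibly) / a `counts_matrix`.
#' @export
write_counts_mtx <- function(x, dir) {
  stopifnot(inherits(x, "counts_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(as.matrix(x$counts), sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  readr::write_tsv(tibble::tibble(gene_id = rownames(x$counts)),
                   file.path(dir, "genes.tsv"))
  readr::write_tsv(
    tibble::tibble(cell_id = colnames(x$counts),
                   plate_id = unname(x$plate),
                   size_factor = if (is.null(x$size_factors)) NA_real_
                                 else unname(x$size_factors)),
    file.path(dir, "cells.tsv"))
  invisible(dir)
}

#' @rdname write_counts_mtx
#' @export
read_counts_mtx <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  genes <- readr::read_tsv(file.path(dir, "genes.tsv"),
                           show_col_types = FALSE)
  cells <- readr::read_tsv(file.path(dir, "cells.tsv"),
                           show_col_types = FALSE)
  dimnames(m) <- list(genes$gene_id, cells$cell_id)
  sf <- cells$size_factor
  counts_matrix(m, plate = setNames(cells$plate_id, cells$cell_id),
                size_factors = if (!all(is.na(sf)))
                  setNames(sf, cells$cell_id))
}

#' Read counts from one wide TSV
#'
#' Expects a `gene_id` column followed by one column per cell; plate labels
#' come from a separate two-column table (`cell_id`, `plate_id`).
#'
#' @param path Wide TSV of counts.
#' @param cells_path TSV with `cell_id` and `plate_id`.
#' @return A `counts_matrix`.
#' @export
read_counts_tsv <- function(path, cells_path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide[[1]]
  cells <- readr::read_tsv(cells_path, show_col_types = FALSE)
  counts_matrix(m, plate = setNames(cells$plate_id, cells$cell_id))
}
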