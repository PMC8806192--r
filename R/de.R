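# Differential expression between G2/M cells and early-G1 cells: a
# negative-binomial GLM likelihood-ratio test with method-of-moments
# dispersion, the 2-fold change rule, and Bonferroni family-wise control.

#' Partition cells for differential expression
#'
#' Only the first 4 hr of G1 are covered by every plate, so DE compares all
#' G2/M cells against G1 cells with assigned time at most `g1_horizon`
#' minutes. Later G1 cells are excluded here but retained for the spline and
#' kinetic-model stages.
#'
#' @param records Timed cell table from [assign_times()] (needs `cell_id`,
#'   `gate_label`, `cell_cycle_time`).
#' @param g1_horizon Maximum G1 time (min) for inclusion; default 240.
#' @return A list with cell-id vectors `g2m` and `g1`.
#' @export
select_de_cells <- function(records, g1_horizon = 240) {
  g2m <- records$cell_id[records$gate_label == "G2M"]
  g1 <- records$cell_id[records$gate_label == "G1" &
                          !is.na(records$cell_cycle_time) &
                          records$cell_cycle_time <= g1_horizon]
  if (length(g2m) == 0) stop("no G2/M cells in partition", call. = FALSE)
  if (length(g1) == 0)
    stop("no G1 cells within ", g1_horizon, " min", call. = FALSE)
  list(g2m = g2m, g1 = g1)
}

#' Negative-binomial two-group test for one gene
#'
#' Fits a negative-binomial GLM of raw counts on group with
#' `log(size_factor)` offset and tests the group term against the
#' intercept-only model by likelihood ratio (chi-squared, 1 df). The
#' dispersion is estimated by method of moments from the group means and
#' held fixed (floored at 1e-8). The fold change is the ratio of
#' size-factor-normalized group means with pseudocount 0.1 (G1 over G2/M).
#'
#' @param y Raw counts for one gene (vector over cells).
#' @param group Factor/character with levels `G2M` (reference) and `G1`.
#' @param size_factors Positive per-cell size factors.
#' @param pseudocount Added to both normalized means for the fold change.
#' @return A one-row tibble: `mean_g2m`, `mean_g1`, `log2_fold_change`,
#'   `p_value`, `flag` (`ok` or `all_zero`).
#' @export
nb_two_group_test <- function(y, group, size_factors, pseudocount = 0.1) {
  group <- factor(group, levels = c("G2M", "G1"))
  stopifnot(length(y) == length(group), length(y) == length(size_factors),
            !anyNA(group))
  norm <- y / size_factors
  mean_g2m <- mean(norm[group == "G2M"])
  mean_g1 <- mean(norm[group == "G1"])
  l2fc <- log2((mean_g1 + pseudocount) / (mean_g2m + pseudocount))
  if (all(y == 0))
    return(tibble::tibble(mean_g2m = 0, mean_g1 = 0, log2_fold_change = 0,
                          p_value = 1, flag = "all_zero"))
  # method-of-moments dispersion from group-wise fitted means
  q <- c(G2M = sum(y[group == "G2M"]) / sum(size_factors[group == "G2M"]),
         G1 = sum(y[group == "G1"]) / sum(size_factors[group == "G1"]))
  mu <- q[as.character(group)] * size_factors
  phi <- max((sum((y - mu)^2) - sum(mu)) / sum(mu^2), 1e-8)
  fit <- suppressWarnings(
    glm(y ~ group + offset(log(size_factors)),
        family = MASS::negative.binomial(theta = 1 / phi)))
  stat <- max(fit$null.deviance - fit$deviance, 0)
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  tibble::tibble(mean_g2m = mean_g2m, mean_g1 = mean_g1,
                 log2_fold_change = l2fc, p_value = p, flag = "ok")
}

#' Wilcoxon rank-sum fallback test for one gene
#'
#' Distribution-free alternative to [nb_two_group_test()] on size-factor
#' normalized counts, for robustness comparison.
#'
#' @inheritParams nb_two_group_test
#' @return A one-row tibble matching [nb_two_group_test()].
#' @export
wilcoxon_two_group_test <- function(y, group, size_factors,
                                    pseudocount = 0.1) {
  group <- factor(group, levels = c("G2M", "G1"))
  norm <- y / size_factors
  mean_g2m <- mean(norm[group == "G2M"])
  mean_g1 <- mean(norm[group == "G1"])
  l2fc <- log2((mean_g1 + pseudocount) / (mean_g2m + pseudocount))
  if (all(y == 0))
    return(tibble::tibble(mean_g2m = 0, mean_g1 = 0, log2_fold_change = 0,
                          p_value = 1, flag = "all_zero"))
  p <- suppressWarnings(
    stats::wilcox.test(norm[group == "G1"], norm[group == "G2M"])$p.value)
  tibble::tibble(mean_g2m = mean_g2m, mean_g1 = mean_g1,
                 log2_fold_change = l2fc, p_value = p, flag = "ok")
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param n_tests Number of tests (>= 1); with the study's 3985 detected
#'   genes this gives 1.2547e-5.
#' @return `alpha / n_tests`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 3985)
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  if (length(n_tests) != 1L || is.na(n_tests) || n_tests < 1)
    stop("`n_tests` must be a single integer >= 1", call. = FALSE)
  alpha / n_tests
}

#' Test all genes for G2/M vs G1 differential expression
#'
#' @param x A [counts_matrix] with size factors.
#' @param partition Cell partition from [select_de_cells()].
#' @param genes Gene ids to test (typically the detection-filtered set);
#'   default all genes.
#' @param test `"nb"` (negative-binomial GLM LRT) or `"wilcoxon"`.
#' @param pseudocount Fold-change pseudocount.
#' @return Tibble with one row per gene: `gene_id`, `mean_g2m`, `mean_g1`,
#'   `log2_fold_change`, `p_value`, `flag`.
#' @export
test_differential_expression <- function(x, partition,
                                         genes = rownames(x$counts),
                                         test = c("nb", "wilcoxon"),
                                         pseudocount = 0.1) {
  stopifnot(inherits(x, "counts_matrix"))
  test <- match.arg(test)
  if (is.null(x$size_factors))
    stop("size factors not computed", call. = FALSE)
  cells <- c(partition$g2m, partition$g1)
  cells <- intersect(cells, colnames(x$counts))
  group <- ifelse(cells %in% partition$g2m, "G2M", "G1")
  m <- umi_counts(x)[genes, cells, drop = FALSE]
  sf <- x$size_factors[cells]
  fn <- if (test == "nb") nb_two_group_test else wilcoxon_two_group_test
  res <- purrr::map_dfr(seq_along(genes), function(i)
    fn(m[i, ], group, sf, pseudocount))
  dplyr::bind_cols(tibble::tibble(gene_id = genes), res)
}

#' Classify DE genes by fold change and Bonferroni threshold
#'
#' A gene is `down` (in G1 relative to G2/M) if its fold change is at most
#' `1/fold_cut` and its p-value at most `threshold`; `up` if the fold change
#' is at least `fold_cut` with the same p rule; otherwise `ns`.
#'
#' @param results Tibble from [test_differential_expression()].
#' @param fold_cut Fold-change cutoff (default 2).
#' @param threshold P-value threshold, e.g. [bonferroni_threshold()].
#' @return `results` with a `direction` column (`up`, `down`, `ns`).
#' @export
classify_de_genes <- function(results, fold_cut = 2, threshold) {
  stopifnot(fold_cut >= 1, threshold > 0)
  fc <- 2^results$log2_fold_change
  dplyr::mutate(results, direction = dplyr::case_when(
    fc <= 1 / fold_cut & .data$p_value <= threshold ~ "down",
    fc >= fold_cut & .data$p_value <= threshold ~ "up",
    TRUE ~ "ns"))
}
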