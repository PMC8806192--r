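# Two-phase mRNA decay kinetics. mRNA obeys dm/dt = mu - gamma * m with a
# switch at t_onset: levels are constant at m0 before onset and relax
# exponentially towards the new steady state mu/gamma afterwards. Fitting is
# a grid search over onset time (0-370 min, 10-min steps) with bounded
# least squares over (m0, mu, gamma) at each grid point; half-life =
# ln(2) / gamma.

#' Evaluate the two-phase decay model
#'
#' `m(t) = m0` for `t < t_onset`;
#' `m(t) = mu/gamma + (m0 - mu/gamma) * exp(-gamma * (t - t_onset))` for
#' `t >= t_onset`. Continuous in `t` at the onset.
#'
#' @param t Time(s) in minutes since metaphase (may be negative for the
#'   nominal pre-metaphase placement of G2/M cells).
#' @param m0 Pre-onset mRNA level (expression units, > 0).
#' @param mu Synthesis rate (expression units / min, >= 0).
#' @param gamma Degradation rate (1/min, > 0).
#' @param t_onset Onset time (min).
#' @return Model mRNA level(s).
#' @export
#' @examples
#' decay_model(60, m0 = 100, mu = 0, gamma = log(2) / 60, t_onset = 0)  # 50
decay_model <- function(t, m0, mu, gamma, t_onset) {
  if (any(gamma <= 0)) stop("`gamma` must be > 0", call. = FALSE)
  ss <- mu / gamma
  ifelse(t < t_onset, m0, ss + (m0 - ss) * exp(-gamma * (t - t_onset)))
}

#' Half-life from a degradation rate
#'
#' @param gamma Degradation rate (1/min, > 0).
#' @return `ln(2) / gamma` in minutes.
#' @export
#' @examples
#' half_life(log(2) / 60)  # 60
half_life <- function(gamma) {
  if (any(!is.finite(gamma)) || any(gamma <= 0))
    stop("`gamma` must be > 0", call. = FALSE)
  log(2) / gamma
}

# Bounded least squares over (m0, mu, gamma) at one fixed onset time:
# Levenberg-Marquardt with box constraints, with up to 3 perturbed restarts.
fit_at_onset <- function(times, expression, t_onset, gamma_bounds,
                         init = NULL) {
  resid_fn <- function(par)
    expression - decay_model(times, par[1], par[2], par[3], t_onset)
  if (is.null(init)) {
    pre <- expression[times <= t_onset]
    if (length(pre) == 0)
      pre <- expression[times <= quantile(times, 0.1)]
    m0_0 <- max(mean(pre), 1e-6)
    gamma_0 <- log(2) / 60
    late <- expression[times >= quantile(times, 0.9)]
    mu_0 <- gamma_0 * max(mean(late), 0)
    init <- c(m0_0, mu_0, gamma_0)
  }
  lower <- c(1e-8, 0, gamma_bounds[1])
  upper <- c(1e12, 1e12, gamma_bounds[2])
  starts <- list(init,
                 init * c(0.5, 2, 0.5), init * c(2, 0.5, 2),
                 init * c(1, 0.1, 4))
  best <- NULL
  for (s in starts) {
    s <- pmin(pmax(s, lower), upper)
    res <- tryCatch(
      minpack.lm::nls.lm(par = s, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(res)) next
    sse <- sum(res$fvec^2)
    conv <- res$info %in% 1:4  # minpack success codes
    if (is.null(best) || sse < best$sse)
      best <- list(par = unname(res$par), sse = sse, converged = conv)
    if (!is.null(best) && best$converged) break
  }
  if (is.null(best))
    return(list(par = init, sse = Inf, converged = FALSE))
  best
}

#' Fit the two-phase decay model by onset-time grid search
#'
#' For every onset time on the grid, `(m0, mu, gamma)` are fit by bounded
#' nonlinear least squares (initialized from the pre-onset mean, gamma =
#' ln2/60, and the latest-decile mean; up to 3 perturbed restarts on
#' failure); the onset with the smallest sum of squared errors wins, ties
#' (within 1e-9 relative) going to the earliest onset. A fit whose total
#' decline over the observed window is under 1% is flagged non-decaying and
#' pinned at the lower gamma bound with `mu = gamma * m0`.
#'
#' @param times Per-cell cell-cycle times (min); include G2/M cells at their
#'   nominal pre-metaphase time for pre-onset coverage.
#' @param expression Per-cell normalized expression.
#' @param onset_grid Candidate onset times (min); default `seq(0, 370, 10)`.
#' @param gamma_bounds Bounds for gamma (1/min); default `(1e-5, 1]` spans
#'   half-lives from ~0.7 min to ~48 days.
#' @param min_cells Minimum number of cells.
#' @param gene_id Optional label carried into the result.
#' @return A `decay_fit` object with elements `gene_id`, `m0`, `mu`,
#'   `gamma`, `t_onset`, `sse`, `half_life`, `steady_state`, `converged`,
#'   `decaying`, `n_cells`, `onset_profile` (SSE per grid onset), and the
#'   data used.
#' @export
fit_decay <- function(times, expression, onset_grid = seq(0, 370, by = 10),
                      gamma_bounds = c(1e-5, 1), min_cells = 30L,
                      gene_id = NA_character_) {
  ok <- is.finite(times) & is.finite(expression)
  times <- times[ok]; expression <- expression[ok]
  if (length(times) < min_cells)
    stop("need at least ", min_cells, " cells", call. = FALSE)

  fits <- lapply(onset_grid, function(on)
    fit_at_onset(times, expression, on, gamma_bounds))
  sses <- vapply(fits, `[[`, numeric(1), "sse")
  conv <- vapply(fits, `[[`, logical(1), "converged")
  if (!any(is.finite(sses)))
    stop("optimizer failed at every onset grid point", call. = FALSE)
  best_sse <- min(sses)
  # earliest onset among ties within 1e-9 relative
  tie <- which(sses <= best_sse * (1 + 1e-9) + 1e-12)
  pick <- tie[1]
  par <- fits[[pick]]$par
  m0 <- par[1]; mu <- par[2]; gamma <- par[3]
  t_onset <- onset_grid[pick]

  # non-decaying contract: negligible decline over the observed window
  m_start <- decay_model(min(times), m0, mu, gamma, t_onset)
  m_end <- decay_model(max(times), m0, mu, gamma, t_onset)
  decaying <- is.finite(m_start) && m_start > 0 &&
    (m_start - m_end) / m_start > 0.01
  if (!decaying) {
    m0 <- mean(expression)
    gamma <- gamma_bounds[1]
    mu <- gamma * m0
    r <- expression - m0
    best_sse <- sum(r * r)
    t_onset <- onset_grid[1]
  }
  structure(list(gene_id = gene_id, m0 = m0, mu = mu, gamma = gamma,
                 t_onset = t_onset, sse = best_sse,
                 half_life = log(2) / gamma, steady_state = mu / gamma,
                 converged = if (decaying) conv[pick] else TRUE,
                 decaying = decaying, n_cells = length(times),
                 onset_profile = tibble::tibble(t_onset = onset_grid,
                                                sse = sses,
                                                converged = conv),
                 data = tibble::tibble(t = times, expression = expression)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("<decay_fit>", if (!is.na(x$gene_id)) x$gene_id, "\n")
  cat(sprintf("  m0 = %.4g, mu = %.4g, gamma = %.4g /min, t_onset = %g min\n",
              x$m0, x$mu, x$gamma, x$t_onset))
  cat(sprintf("  half-life = %.4g min, steady state = %.4g, SSE = %.4g\n",
              x$half_life, x$steady_state, x$sse))
  cat("  converged:", x$converged, "| decaying:", x$decaying,
      "| n =", x$n_cells, "\n")
  invisible(x)
}

#' Fit decay kinetics for many genes
#'
#' @param x A [counts_matrix] with size factors.
#' @param times Named per-cell times (min), including the nominal
#'   pre-metaphase time for G2/M cells; `NA` cells are dropped.
#' @param genes Gene ids to fit (typically the downregulated set).
#' @param ... Passed to [fit_decay()].
#' @return A tibble with one row per gene (the [tidy()] of each fit).
#' @export
fit_decay_genes <- function(x, times, genes, ...) {
  stopifnot(inherits(x, "counts_matrix"))
  times <- times[intersect(names(times), colnames(x$counts))]
  times <- times[is.finite(times)]
  expr <- normalized_counts(x)[genes, names(times), drop = FALSE]
  purrr::map_dfr(seq_along(genes), function(i)
    tidy(fit_decay(times, expr[i, ], gene_id = genes[i], ...)))
}

#' Summarize decay fits
#'
#' Median half-life over converged decaying genes, the onset-time histogram,
#' and (when wave calls are supplied) per-wave-group half-life summaries.
#'
#' @param fits Tibble from [fit_decay_genes()].
#' @param waves Optional wave-call tibble from [call_waves()].
#' @return A `decay_summary` list: `n_genes`, `n_converged`,
#'   `median_half_life`, `onset_histogram`, and optionally `by_group`.
#' @export
summarize_fits <- function(fits, waves = NULL) {
  use <- fits[fits$converged & fits$decaying, , drop = FALSE]
  if (nrow(use) == 0) stop("no converged decaying fits", call. = FALSE)
  out <- list(
    n_genes = nrow(fits), n_converged = sum(fits$converged),
    n_decaying = sum(fits$decaying & fits$converged),
    median_half_life = median(use$half_life),
    onset_histogram = dplyr::count(use, .data$t_onset, name = "n_genes"))
  if (!is.null(waves)) {
    joined <- dplyr::inner_join(use, waves, by = "gene_id")
    out$by_group <- joined |>
      dplyr::group_by(.data$wave_group) |>
      dplyr::summarise(n = dplyr::n(),
                       median_half_life = median(.data$half_life),
                       median_t_onset = median(.data$t_onset),
                       .groups = "drop")
  }
  structure(out, class = "decay_summary")
}

#' @export
print.decay_summary <- function(x, ...) {
  cat("<decay_summary>", x$n_decaying, "decaying /", x$n_converged,
      "converged /", x$n_genes, "genes\n")
  cat("  median half-life:", signif(x$median_half_life, 4), "min\n")
  if (!is.null(x$by_group)) print(x$by_group)
  invisible(x)
}

#' G1/G2 labeled-transcript transcription ratios
#'
#' For metabolically labeled (e.g. EU pulse) transcript counts, computes per
#' gene the mean labeled count over G1 cells divided by the mean over G2
#' cells. Genes whose G2 mean is zero are marked excluded and get no ratio.
#'
#' @param labeled Genes x cells matrix of labeled-transcript counts.
#' @param g1_cells,g2_cells Cell ids (column names) of the two phases.
#' @return A tibble: `gene_id`, `mean_labeled_g1`, `mean_labeled_g2`,
#'   `ratio`, `excluded`.
#' @export
transcription_ratio <- function(labeled, g1_cells, g2_cells) {
  g1_cells <- intersect(g1_cells, colnames(labeled))
  g2_cells <- intersect(g2_cells, colnames(labeled))
  if (length(g1_cells) == 0 || length(g2_cells) == 0)
    stop("both phase groups must be non-empty", call. = FALSE)
  m1 <- rowMeans(labeled[, g1_cells, drop = FALSE])
  m2 <- rowMeans(labeled[, g2_cells, drop = FALSE])
  excluded <- m2 == 0
  tibble::tibble(gene_id = rownames(labeled),
                 mean_labeled_g1 = unname(m1),
                 mean_labeled_g2 = unname(m2),
                 ratio = unname(ifelse(excluded, NA_real_, m1 / m2)),
                 excluded = unname(excluded))
}
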