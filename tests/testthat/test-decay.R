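test_that("the two-phase model obeys its limits and continuity", {
  expect_equal(decay_model(c(-10, 0, 79.9), 100, 0.2, 0.02, 80),
               rep(100, 3))
  expect_equal(decay_model(60, 100, 0, log(2) / 60, 0), 50)
  # steady-state limit
  expect_equal(decay_model(1e5, 100, 0.2, 0.02, 0), 10, tolerance = 1e-6)
  # continuity at the onset
  eps <- 1e-9
  left <- decay_model(80 - eps, 100, 0.2, 0.02, 80)
  right <- decay_model(80 + eps, 100, 0.2, 0.02, 80)
  expect_lt(abs(left - right), 1e-6)
  expect_error(decay_model(10, 100, 0.2, 0, 80), "gamma")
})

test_that("half-life inverts the degradation rate", {
  expect_equal(half_life(log(2)), 1)
  expect_equal(half_life(log(2) / 60), 60)
  expect_equal(signif(half_life(0.011271), 3), 61.5)
  for (h in c(1, 30, 61.5, 600))
    expect_equal(half_life(log(2) / h), h)
  # strictly decreasing in gamma
  g <- c(0.001, 0.01, 0.1, 1)
  expect_true(all(diff(half_life(g)) < 0))
  expect_error(half_life(0), "gamma")
  expect_error(half_life(-1), "gamma")
})

test_that("noiseless model data are fit back to the exact parameters", {
  t <- seq(0, 399, length.out = 400)
  y <- decay_model(t, 100, 0.2, 0.02, 80)
  fit <- fit_decay(t, y)
  expect_equal(fit$t_onset, 80)
  expect_lt(abs(fit$m0 / 100 - 1), 1e-3)
  expect_lt(abs(fit$mu / 0.2 - 1), 1e-3)
  expect_lt(abs(fit$gamma / 0.02 - 1), 1e-3)
  expect_true(fit$converged)
  expect_true(fit$decaying)
  expect_equal(fit$half_life, log(2) / fit$gamma)
})

test_that("rescaling expression rescales m0 and mu but not gamma or onset", {
  t <- seq(0, 399, length.out = 400)
  y <- decay_model(t, 100, 0.2, 0.02, 80)
  f1 <- fit_decay(t, y)
  f2 <- fit_decay(t, 5 * y)
  expect_equal(f2$t_onset, f1$t_onset)
  expect_equal(f2$gamma, f1$gamma, tolerance = 1e-6)
  expect_equal(f2$m0, 5 * f1$m0, tolerance = 1e-6)
  expect_equal(f2$mu, 5 * f1$mu, tolerance = 1e-6)
})

test_that("a constant gene is pinned non-decaying at the lower gamma bound", {
  t <- seq(-10, 500, length.out = 200)
  fit <- fit_decay(t, rep(42, 200))
  expect_false(fit$decaying)
  expect_equal(fit$gamma, 1e-5)
  expect_equal(fit$m0, 42)
  expect_equal(fit$steady_state, 42)
})

test_that("exact SSE ties resolve to the earliest onset", {
  # data only after t = 100: every onset up to 100 fits the same pure
  # exponential exactly, so the SSE profile is tied (to optimizer precision)
  # and the earliest onset must win
  t <- seq(100, 500, length.out = 200)
  y <- 80 * exp(-0.01 * t)
  fit <- fit_decay(t, y)
  profile <- fit$onset_profile
  ties <- profile$t_onset[profile$sse <=
                            min(profile$sse) * (1 + 1e-9) + 1e-12]
  expect_gte(length(ties), 2)
  expect_true(all(ties <= 100))
  expect_equal(fit$t_onset, min(ties))
})

test_that("grid-search fit matches the brute-force lattice oracle", {
  set.seed(21)
  times <- c(rep(-10, 20), runif(180, 0, 500))
  genes <- list(
    list(m0 = 100, mu = 0.10, gamma = 0.010, t_onset = 0),
    list(m0 = 60, mu = 0.30, gamma = 0.020, t_onset = 50),
    list(m0 = 150, mu = 0.05, gamma = 0.008, t_onset = 80),
    list(m0 = 80, mu = 0.40, gamma = 0.030, t_onset = 150),
    list(m0 = 120, mu = 0.20, gamma = 0.015, t_onset = 200))
  for (g in genes) {
    y <- decay_model(times, g$m0, g$mu, g$gamma, g$t_onset) +
      rnorm(length(times), 0, 0.02 * g$m0)
    fit <- fit_decay(times, y)
    gamma_grid <- exp(seq(log(1e-3), log(0.2), length.out = 60))
    m0_grid <- seq(0.3 * max(y), 1.2 * max(y), length.out = 50)
    ss_grid <- seq(0, 0.6 * max(y), length.out = 40)
    oracle <- oracle_lattice_fit(times, y, gamma_grid = gamma_grid,
                                 m0_grid = m0_grid, ss_grid = ss_grid)
    expect_equal(fit$t_onset, oracle$t_onset)
    # sandwich within lattice resolution: the continuous optimum can only
    # improve on the lattice optimum, and the lattice optimum can only
    # improve on the continuous solution snapped to the nearest lattice node
    expect_lte(fit$sse, oracle$sse * (1 + 1e-6))
    snap <- function(v, grid) grid[which.min(abs(grid - v))]
    g_snap <- snap(fit$gamma, gamma_grid)
    m0_snap <- snap(fit$m0, m0_grid)
    ss_snap <- snap(fit$steady_state, ss_grid)
    r <- y - decay_model(times, m0_snap, ss_snap * g_snap, g_snap,
                         fit$t_onset)
    expect_lte(oracle$sse, sum(r * r) * (1 + 1e-9))
  }
})

test_that("gamma error grows with count noise (sanity ordering)", {
  errs <- vapply(c(0.1, 0.6), function(phi) {
    cfg <- small_sim_config(n_g1_cells = 400, nb_dispersion = phi, seed = 17,
                            n_genes_immediate = 8, n_genes_delayed = 8)
    truth <- simulate_ground_truth(cfg)
    cm <- compute_size_factors(simulate_counts(cfg, truth))
    times <- truth_times(truth, cm)
    dec <- truth$genes[truth$genes$wave_group %in%
                         c("immediate", "delayed"), ]
    fits <- fit_decay_genes(cm, times, dec$gene_id)
    j <- dplyr::inner_join(fits, dec, by = "gene_id",
                           suffix = c("_hat", "_true"))
    sqrt(mean((j$gamma_hat / j$gamma_true - 1)^2))
  }, numeric(1))
  expect_gte(errs[2], errs[1])
})

test_that("fit summaries report the median half-life and onset histogram", {
  fits <- tibble::tibble(
    gene_id = c("a", "b", "c"),
    m0 = 10, mu = 0, gamma = log(2) / c(10, 61.5, 200),
    t_onset = c(0, 10, 80), sse = 1,
    half_life = c(10, 61.5, 200), steady_state = 0,
    converged = TRUE, decaying = TRUE)
  s <- summarize_fits(fits)
  expect_equal(s$median_half_life, 61.5)
  expect_equal(sum(s$onset_histogram$n_genes), 3)
  none <- dplyr::mutate(fits, converged = FALSE)
  expect_error(summarize_fits(none), "no converged")
})

test_that("transcription ratios follow the G2-zero exclusion rule", {
  labeled <- rbind(equal = c(4, 4, 4, 4), halved = c(2, 2, 4, 4),
                   g2zero = c(5, 5, 0, 0))
  colnames(labeled) <- c("a", "b", "c", "d")
  out <- transcription_ratio(labeled, g1_cells = c("a", "b"),
                             g2_cells = c("c", "d"))
  expect_equal(out$ratio[out$gene_id == "equal"], 1)
  expect_equal(out$ratio[out$gene_id == "halved"], 0.5)
  expect_true(out$excluded[out$gene_id == "g2zero"])
  expect_true(is.na(out$ratio[out$gene_id == "g2zero"]))
  expect_error(transcription_ratio(labeled, character(0), c("c", "d")),
               "non-empty")
})

test_that("tidy and glance expose decay-fit parameters", {
  t <- seq(0, 399, length.out = 100)
  fit <- fit_decay(t, decay_model(t, 50, 0.1, 0.02, 40), gene_id = "g1")
  td <- tidy(fit)
  expect_equal(td$gene_id, "g1")
  expect_equal(td$t_onset, 40)
  expect_named(glance(fit), c("sse", "n_cells", "converged", "decaying"))
})
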