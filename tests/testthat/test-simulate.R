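test_that("generator is deterministic under a fixed seed", {
  cfg <- small_sim_config(seed = 42)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(umi_counts(a$counts), umi_counts(b$counts))
  expect_equal(a$traces, b$traces)
  expect_equal(a$facs, b$facs)
  expect_equal(a$truth$genes, b$truth$genes)
})

test_that("zero heterogeneity and zero noise collapse all traces onto one", {
  cfg <- small_sim_config(trace_amplitude_cv = 0, measurement_noise_sd = 0,
                          g2_rise_sd = 0)
  tr <- simulate_fucci_traces(cfg)$traces
  per_time_spread <- tapply(tr$g1, tr$t_min, function(v) diff(range(v)))
  expect_true(all(per_time_spread == 0))
})

test_that("raw G2 channel is constructed as crosstalk fraction of G1", {
  cfg <- small_sim_config(measurement_noise_sd = 0)
  truth <- simulate_ground_truth(cfg)
  snap <- simulate_facs_snapshot(cfg, truth)
  g1_rows <- snap[snap$gate_label == "G1", ]
  # G1 cells have no true G2 signal, so raw G2 is pure crosstalk
  expect_equal(g1_rows$g2_raw, 0.31 * g1_rows$g1_raw, tolerance = 1e-12)
  # and the correction recovers the true (zero) signal exactly
  expect_equal(correct_crosstalk(g1_rows$g1_raw, g1_rows$g2_raw),
               rep(0, nrow(g1_rows)), tolerance = 1e-12)
})

test_that("snapshot intensities are read off the true accumulation curve", {
  cfg <- small_sim_config(measurement_noise_sd = 0)
  truth <- simulate_ground_truth(cfg)
  snap <- simulate_facs_snapshot(cfg, truth)
  j <- merge(snap, truth$cells, by = "cell_id")
  j <- j[j$gate_label == "G1", ]
  s <- mg1kinetics:::fucci_true_curve(cfg)
  expect_equal(j$g1_raw, j$amplitude * s(j$cell_cycle_time),
               tolerance = 1e-12)
})

test_that("with no G1 cells the snapshot holds only G2M and early-S gates", {
  cfg <- small_sim_config(n_g1_cells = 0, qc_spikeins = FALSE)
  snap <- simulate_facs_snapshot(cfg)
  expect_setequal(unique(snap$gate_label), c("G2M", "early_S"))
})

test_that("a different seed redraws snapshot noise but not supplied truth", {
  cfg1 <- small_sim_config(seed = 1)
  truth <- simulate_ground_truth(cfg1)
  cfg2 <- small_sim_config(seed = 2)
  s1 <- simulate_facs_snapshot(cfg1, truth)
  s2 <- simulate_facs_snapshot(cfg2, truth)
  expect_false(isTRUE(all.equal(s1$g1_raw, s2$g1_raw)))
  expect_identical(s1$cell_id, s2$cell_id)  # same cells, same true times
})

test_that("counts obey the NB mean-variance law and its Poisson limit", {
  base <- list(n_plates = 1L, n_g2m_cells = 1200L, n_g1_cells = 0L,
               n_early_s_cells = 0L, n_genes_immediate = 0L,
               n_genes_delayed = 0L, n_genes_stable = 5L, n_genes_low = 0L,
               capture_cv = 0, qc_spikeins = FALSE, rng_seed = 9L)
  for (phi in c(0.4, 0)) {
    cfg <- do.call(simulation_config, c(base, list(nb_dispersion = phi)))
    truth <- simulate_ground_truth(cfg)
    m <- umi_counts(simulate_counts(cfg, truth))
    n <- ncol(m)
    for (g in seq_len(nrow(m))) {
      x <- m[g, ]
      mu_true <- truth$genes$m0[g]
      var_true <- mu_true + phi * mu_true^2
      expect_lt(abs(mean(x) - mu_true), 3 * sd(x) / sqrt(n))
      se_var <- sqrt((mean((x - mean(x))^4) - stats::var(x)^2) / n)
      expect_lt(abs(stats::var(x) - var_true), 3 * se_var)
    }
  }
})

test_that("binned empirical means track the closed-form decay trajectory", {
  cfg <- simulation_config(
    n_plates = 1L, n_g2m_cells = 60L, n_g1_cells = 900L,
    n_early_s_cells = 0L, n_genes_immediate = 5L, n_genes_delayed = 0L,
    n_genes_stable = 20L, n_genes_low = 0L, qc_spikeins = FALSE,
    m0_meanlog = log(60), m0_sdlog = 0.3, rng_seed = 7L)
  truth <- simulate_ground_truth(cfg)
  m <- umi_counts(simulate_counts(cfg, truth))
  cells <- truth$cells[truth$cells$phase == "G1", ]
  gene <- truth$genes[truth$genes$wave_group == "immediate", ][1, ]
  x <- m[gene$gene_id, cells$cell_id]
  bins <- cut(cells$cell_cycle_time, seq(0, 540, by = 30))
  for (b in levels(bins)) {
    idx <- which(bins == b)
    if (length(idx) < 20) next
    model_mean <- mean(decay_model(cells$cell_cycle_time[idx], gene$m0,
                                   gene$mu, gene$gamma, gene$t_onset))
    se <- sd(x[idx]) / sqrt(length(idx))
    expect_lt(abs(mean(x[idx]) - model_mean), 3 * se)
  }
})

test_that("ground-truth export round-trips exactly and keeps cardinality", {
  cfg <- small_sim_config()
  truth <- simulate_ground_truth(cfg)
  dir <- withr::local_tempdir()
  export_truth(truth, dir)
  back <- read_truth(dir)
  expect_equal(as.data.frame(back$genes), as.data.frame(truth$genes))
  expect_equal(as.data.frame(back$cells), as.data.frame(truth$cells))
  expect_equal(nrow(back$genes),
               cfg$n_genes_immediate + cfg$n_genes_delayed +
                 cfg$n_genes_stable + cfg$n_genes_low)

  empty <- simulate_ground_truth(small_sim_config(
    n_genes_immediate = 0, n_genes_delayed = 0, n_genes_stable = 0,
    n_genes_low = 0))
  dir2 <- withr::local_tempdir()
  export_truth(empty, dir2)
  expect_equal(nrow(read_truth(dir2)$genes), 0)
})

test_that("config validation rejects invalid parameters", {
  expect_error(simulation_config(n_plates = 0), "n_plates")
  expect_error(simulation_config(crosstalk_fraction = 1.2), "crosstalk")
  expect_error(simulation_config(nb_dispersion = -1), "nb_dispersion")
  expect_error(simulation_config(measurement_noise_sd = -1), "noise")
  expect_error(simulation_config(trace_time_step = 0), "time_step")
  expect_error(simulation_config(g1_time_range = c(0, 600)), "g1_time_range")
})

test_that("counts matrix round-trips through MatrixMarket sidecar files", {
  cfg <- small_sim_config()
  cm <- simulate_counts(cfg)
  dir <- withr::local_tempdir()
  write_counts_mtx(cm, dir)
  back <- read_counts_mtx(dir)
  expect_equal(umi_counts(back), umi_counts(cm))
  expect_equal(back$plate, cm$plate)
})
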