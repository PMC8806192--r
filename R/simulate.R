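# Synthetic FUCCI + SORT-seq experiment generator with full ground truth.
#
# The generator emulates the study design downstream stages expect: three
# 384-well plates of FACS-sorted cells (~100 G2/M plus ~755 G1 cells spanning
# 0-540 min after metaphase), live-cell FUCCI-G1 traces aligned at the
# metaphase-to-anaphase transition, 31% G1->G2 channel crosstalk, and
# negative-binomial UMI counts whose per-gene means follow the two-phase
# decay model with onset-time modes at mitotic exit (~10 min) and early G1
# (~80 min).

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic experiment. Defaults reproduce the
#' study conditions: 3 plates, 100 G2/M cells, 755 G1 cells uniform on
#' 0-540 min, two onset-time modes (10 and 80 min), negative-binomial counts
#' with dispersion 0.3 (variance = mu + 0.3 mu^2), 20% log-normal per-cell
#' capture-efficiency variation, and 31% G1-into-G2 channel crosstalk.
#'
#' @param n_plates Number of 384-well plates (round-robin cell assignment).
#' @param n_g2m_cells,n_g1_cells,n_early_s_cells Sorted cells per gate. The
#'   early-S cells appear only in the FACS snapshot (they anchor the
#'   normalization gate) and are never sequenced.
#' @param g1_time_range Minutes after metaphase spanned by G1 cells,
#'   within \[0, 540\].
#' @param n_genes_immediate,n_genes_delayed,n_genes_stable,n_genes_low Gene
#'   panel sizes: decaying genes with mitotic-exit or early-G1 onset, stable
#'   genes, and low-expression genes that should fail the detection filter.
#' @param onset_mode_immediate,onset_sd_immediate Mean/SD (min) of true onset
#'   times for the immediate wave.
#' @param onset_mode_delayed,onset_sd_delayed Same for the delayed wave.
#' @param nb_dispersion NB dispersion phi: variance = mu + phi * mu^2;
#'   phi -> 0 is the Poisson limit.
#' @param capture_cv Coefficient of variation of log-normal per-cell capture
#'   efficiency (mean 1).
#' @param crosstalk_fraction Fraction of the G1 channel bleeding into the raw
#'   G2 channel.
#' @param trace_amplitude_cv Per-cell FUCCI-G1 amplitude CV (log-normal).
#' @param measurement_noise_sd Additive Gaussian intensity noise, channel
#'   units.
#' @param m0_meanlog,m0_sdlog Log-normal draw for pre-onset expression m0.
#' @param halflife_median,halflife_sdlog Log-normal draw for true half-lives
#'   (min); gamma = ln(2) / half-life, clipped to (1e-5, 1\].
#' @param residual_frac_range Uniform range of the post-decay steady state as
#'   a fraction of m0 (steady state = mu / gamma).
#' @param g2m_nominal_time Nominal pre-metaphase time (min) at which G2/M
#'   cells are placed for count generation and model fitting.
#' @param qc_spikeins If `TRUE`, add `n_qc_low` cells with UMI totals below
#'   and `n_qc_high` cells above the QC bounds so the cell filter has
#'   positives to act on.
#' @param n_qc_low,n_qc_high Numbers of QC spike-in cells.
#' @param qc_low_total_range,qc_high_total_range Target UMI-total ranges for
#'   the spike-ins.
#' @param n_traces Number of live-cell FUCCI traces.
#' @param trace_time_step,trace_max_time Trace sampling interval and end
#'   (min).
#' @param curve_coefficients Order-3 polynomial coefficients (intercept,
#'   linear, quadratic, cubic) of the true dimensionless FUCCI-G1
#'   accumulation curve; must be monotone increasing on the G1 range.
#' @param base_amplitude Mean per-cell FUCCI-G1 amplitude (intensity units).
#' @param g2_high_level Mean FUCCI-G2 intensity of G2/M cells.
#' @param g2_rise_time,g2_rise_sd Mean/SD (min) of the per-trace time at
#'   which FUCCI-G2 starts rising (end of G1); traces are clipped there
#'   during calibration.
#' @param rng_seed Integer seed; all generator randomness derives from it.
#'
#' @return A `simulation_config` list.
#' @export
#' @examples
#' cfg <- simulation_config(n_g1_cells = 50, n_g2m_cells = 10, rng_seed = 7)
#' cfg$crosstalk_fraction
simulation_config <- function(n_plates = 3L,
                              n_g2m_cells = 100L,
                              n_g1_cells = 755L,
                              n_early_s_cells = 60L,
                              g1_time_range = c(0, 540),
                              n_genes_immediate = 60L,
                              n_genes_delayed = 60L,
                              n_genes_stable = 2000L,
                              n_genes_low = 10L,
                              onset_mode_immediate = 10,
                              onset_sd_immediate = 5,
                              onset_mode_delayed = 80,
                              onset_sd_delayed = 15,
                              nb_dispersion = 0.3,
                              capture_cv = 0.2,
                              crosstalk_fraction = 0.31,
                              trace_amplitude_cv = 0.2,
                              measurement_noise_sd = 2,
                              m0_meanlog = log(15),
                              m0_sdlog = 0.7,
                              halflife_median = 60,
                              halflife_sdlog = 0.35,
                              residual_frac_range = c(0.02, 0.15),
                              g2m_nominal_time = -10,
                              qc_spikeins = TRUE,
                              n_qc_low = 20L,
                              n_qc_high = 10L,
                              qc_low_total_range = c(1000, 3000),
                              qc_high_total_range = c(150000, 250000),
                              n_traces = 90L,
                              trace_time_step = 5,
                              trace_max_time = 600,
                              curve_coefficients = c(0, 3.0e-3, 4.0e-6, -5.5e-9),
                              base_amplitude = 100,
                              g2_high_level = 200,
                              g2_rise_time = 540,
                              g2_rise_sd = 20,
                              rng_seed = 1L) {
  cfg <- as.list(environment())
  counts <- c("n_plates", "n_g2m_cells", "n_g1_cells", "n_early_s_cells",
              "n_genes_immediate", "n_genes_delayed", "n_genes_stable",
              "n_genes_low", "n_qc_low", "n_qc_high", "n_traces")
  for (nm in counts) {
    if (length(cfg[[nm]]) != 1L || is.na(cfg[[nm]]) || cfg[[nm]] < 0)
      stop("`", nm, "` must be a single non-negative count", call. = FALSE)
    cfg[[nm]] <- as.integer(cfg[[nm]])
  }
  if (cfg$n_plates == 0L) stop("`n_plates` must be >= 1", call. = FALSE)
  if (g1_time_range[1] < 0 || g1_time_range[2] > 540 ||
      g1_time_range[1] >= g1_time_range[2])
    stop("`g1_time_range` must lie within [0, 540]", call. = FALSE)
  if (nb_dispersion < 0) stop("`nb_dispersion` must be >= 0", call. = FALSE)
  if (crosstalk_fraction < 0 || crosstalk_fraction > 1)
    stop("`crosstalk_fraction` must be in [0, 1]", call. = FALSE)
  if (measurement_noise_sd < 0)
    stop("`measurement_noise_sd` must be >= 0", call. = FALSE)
  if (trace_time_step <= 0)
    stop("`trace_time_step` must be > 0", call. = FALSE)
  if (length(curve_coefficients) != 4L)
    stop("`curve_coefficients` must have 4 elements", call. = FALSE)
  cfg$rng_seed <- as.integer(rng_seed)
  structure(cfg, class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>\n")
  cat("  plates:", x$n_plates,
      "| cells: G2/M", x$n_g2m_cells, "+ G1", x$n_g1_cells,
      "on [", x$g1_time_range[1], ",", x$g1_time_range[2], "] min\n")
  cat("  genes:", x$n_genes_immediate, "immediate /", x$n_genes_delayed,
      "delayed /", x$n_genes_stable, "stable\n")
  cat("  NB dispersion", x$nb_dispersion, "| capture CV", x$capture_cv,
      "| crosstalk", x$crosstalk_fraction, "| seed", x$rng_seed, "\n")
  invisible(x)
}

# Dimensionless true FUCCI-G1 accumulation curve s(t) (monotone on the G1
# range) and its value used for normalization (end of G1 = early-S level).
fucci_true_curve <- function(config) {
  cf <- config$curve_coefficients
  function(t) cf[1] + cf[2] * t + cf[3] * t^2 + cf[4] * t^3
}

# True normalized curve p(t) = s(t) / s(t_end): early-S mean maps to 1.
fucci_true_normalized_curve <- function(config) {
  s <- fucci_true_curve(config)
  ref <- s(config$g1_time_range[2])
  function(t) s(t) / ref
}

lognormal_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate ground truth for a synthetic experiment
#'
#' Draws the per-gene kinetic parameters (`m0`, `mu`, `gamma`, `t_onset`,
#' wave group) and the per-cell attributes (phase, true cell-cycle time,
#' capture efficiency, plate) that the other `simulate_*` functions consume.
#' Deterministic given `config$rng_seed`.
#'
#' @param config A [simulation_config()].
#' @return A list of class `mg1_truth` with tibbles `genes` and `cells`.
#' @export
simulate_ground_truth <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$rng_seed)

  n_dec <- config$n_genes_immediate + config$n_genes_delayed
  n_genes <- n_dec + config$n_genes_stable + config$n_genes_low
  wave <- c(rep("immediate", config$n_genes_immediate),
            rep("delayed", config$n_genes_delayed),
            rep("stable", config$n_genes_stable),
            rep("low", config$n_genes_low))
  onset <- rep(NA_real_, n_genes)
  if (config$n_genes_immediate > 0)
    onset[wave == "immediate"] <- rnorm(config$n_genes_immediate,
                                        config$onset_mode_immediate,
                                        config$onset_sd_immediate)
  if (config$n_genes_delayed > 0)
    onset[wave == "delayed"] <- rnorm(config$n_genes_delayed,
                                      config$onset_mode_delayed,
                                      config$onset_sd_delayed)
  onset <- pmin(pmax(onset, 0), 370)

  m0 <- rlnorm(n_genes, config$m0_meanlog, config$m0_sdlog)
  m0[wave == "low"] <- rlnorm(sum(wave == "low"), log(0.5), 0.5)
  gamma <- rep(NA_real_, n_genes)
  mu <- rep(NA_real_, n_genes)
  dec <- wave %in% c("immediate", "delayed")
  if (any(dec)) {
    hl <- rlnorm(sum(dec), log(config$halflife_median), config$halflife_sdlog)
    gamma[dec] <- pmin(pmax(log(2) / hl, 1e-5), 1)
    resid <- runif(sum(dec), config$residual_frac_range[1],
                   config$residual_frac_range[2])
    mu[dec] <- gamma[dec] * resid * m0[dec]
  }
  genes <- tibble::tibble(
    gene_id = sprintf("GENE%04d", seq_len(n_genes)),
    wave_group = wave, m0 = m0, mu = mu, gamma = gamma, t_onset = onset,
    half_life = log(2) / gamma)

  n_qc <- if (config$qc_spikeins) config$n_qc_low + config$n_qc_high else 0L
  n_cells <- config$n_g2m_cells + config$n_g1_cells +
    config$n_early_s_cells + n_qc
  phase <- c(rep("G2M", config$n_g2m_cells),
             rep("G1", config$n_g1_cells),
             rep("early_S", config$n_early_s_cells),
             rep("G1", n_qc))
  qc_class <- c(rep("ok", config$n_g2m_cells + config$n_g1_cells +
                      config$n_early_s_cells),
                if (config$qc_spikeins)
                  c(rep("low", config$n_qc_low), rep("high", config$n_qc_high)))
  time <- rep(NA_real_, n_cells)
  is_g1 <- phase == "G1"
  time[is_g1] <- runif(sum(is_g1), config$g1_time_range[1],
                       config$g1_time_range[2])
  time[phase == "early_S"] <- config$g1_time_range[2]
  cells <- tibble::tibble(
    cell_id = sprintf("CELL%04d", seq_len(n_cells)),
    plate_id = sprintf("plate%d", (seq_len(n_cells) - 1L) %% config$n_plates + 1L),
    phase = phase,
    cell_cycle_time = time,
    capture_efficiency = lognormal_cv(n_cells, config$capture_cv),
    amplitude = config$base_amplitude *
      lognormal_cv(n_cells, config$trace_amplitude_cv),
    qc_class = qc_class)
  structure(list(genes = genes, cells = cells, config = config),
            class = "mg1_truth")
}

#' Simulate live-cell FUCCI time traces
#'
#' Generates per-cell FUCCI-G1/G2 intensity traces aligned at the
#' metaphase-to-anaphase transition (t = 0), sampled every
#' `config$trace_time_step` minutes. The G1 channel is a per-cell amplitude
#' times the monotone accumulation curve plus Gaussian noise; the raw G2
#' channel contains the true (late-rising) G2 signal plus
#' `crosstalk_fraction` of the measured G1 channel, so the crosstalk
#' correction and end-of-G1 clipping are both exercised.
#'
#' @param config A [simulation_config()].
#' @return A list with `traces` (tibble: `cell_id`, `t_min`, `g1`, `g2_raw`)
#'   and `trace_truth` (tibble: per-trace amplitude and G2 rise time).
#' @export
#' @examples
#' tr <- simulate_fucci_traces(simulation_config(n_traces = 5))
#' head(tr$traces)
simulate_fucci_traces <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$rng_seed + 1L)
  s <- fucci_true_curve(config)
  tt <- seq(0, config$trace_max_time, by = config$trace_time_step)
  n <- config$n_traces
  amp <- config$base_amplitude * lognormal_cv(n, config$trace_amplitude_cv)
  rise <- rnorm(n, config$g2_rise_time, config$g2_rise_sd)
  g2_slope <- config$g2_high_level / 60  # reaches G2/M level in ~1 hr

  per_cell <- function(i) {
    g1_sig <- amp[i] * s(tt)
    g1 <- g1_sig + rnorm(length(tt), 0, config$measurement_noise_sd)
    g2_true <- pmax(0, tt - rise[i]) * g2_slope
    g2_raw <- g2_true + config$crosstalk_fraction * g1 +
      rnorm(length(tt), 0, config$measurement_noise_sd)
    tibble::tibble(cell_id = sprintf("TRACE%03d", i), t_min = tt,
                   g1 = g1, g2_raw = g2_raw)
  }
  traces <- purrr::map_dfr(seq_len(n), per_cell)
  list(traces = traces,
       trace_truth = tibble::tibble(cell_id = sprintf("TRACE%03d", seq_len(n)),
                                    amplitude = amp, g2_rise_time = rise))
}

#' Simulate a FACS snapshot of sorted cells
#'
#' Reads each cell's FUCCI intensities off the true accumulation curve at its
#' true cell-cycle time, adds measurement noise and channel crosstalk, and
#' labels cells with their sort gate. G2/M cells are FUCCI-G1-negative with a
#' high G2 signal; early-S cells sit at the end of G1 with a just-rising G2
#' signal (they make the early-S normalization gate non-empty); G1 cells have
#' no true G2 signal, so their raw G2 channel is pure crosstalk plus noise.
#'
#' @param config A [simulation_config()].
#' @param truth A [simulate_ground_truth()] result (regenerated from `config`
#'   if omitted).
#' @return A tibble with `cell_id`, `plate_id`, `g1_raw`, `g2_raw`,
#'   `gate_label`.
#' @export
simulate_facs_snapshot <- function(config, truth = simulate_ground_truth(config)) {
  stopifnot(inherits(config, "simulation_config"), inherits(truth, "mg1_truth"))
  set.seed(config$rng_seed + 2L)
  s <- fucci_true_curve(config)
  cells <- truth$cells
  n <- nrow(cells)
  g1_sig <- numeric(n)
  idx_g1 <- cells$phase == "G1"
  idx_es <- cells$phase == "early_S"
  g1_sig[idx_g1] <- cells$amplitude[idx_g1] * s(cells$cell_cycle_time[idx_g1])
  g1_sig[idx_es] <- cells$amplitude[idx_es] * s(config$g1_time_range[2])
  g2_true <- numeric(n)
  idx_g2m <- cells$phase == "G2M"
  g2_true[idx_g2m] <- rnorm(sum(idx_g2m), config$g2_high_level,
                            0.1 * config$g2_high_level)
  g2_true[idx_es] <- runif(sum(idx_es), 0.04, 0.09) * config$g2_high_level
  g1_raw <- g1_sig + rnorm(n, 0, config$measurement_noise_sd)
  g2_raw <- g2_true + config$crosstalk_fraction * g1_raw +
    rnorm(n, 0, config$measurement_noise_sd)
  tibble::tibble(cell_id = cells$cell_id, plate_id = cells$plate_id,
                 g1_raw = g1_raw, g2_raw = g2_raw, gate_label = cells$phase)
}

#' Simulate a UMI count matrix from ground truth
#'
#' Counts for gene g in cell c are negative-binomial with mean
#' `capture_efficiency_c * m_g(t_c)` and variance `mu + phi * mu^2`
#' (phi = `nb_dispersion`; Poisson when phi = 0), where `m_g(t)` follows the
#' two-phase decay model (constant `m0` before onset, relaxation towards
#' `mu/gamma` after) and stable genes have constant mean `m0`. G2/M cells are
#' placed at the nominal pre-metaphase time. QC spike-in cells get capture
#' efficiencies tuned so their expected totals fall in the configured
#' out-of-bounds ranges. Early-S (FACS-only) cells are not sequenced.
#'
#' @param config A [simulation_config()].
#' @param truth A [simulate_ground_truth()] result.
#' @return A [counts_matrix] (genes x cells) with plate labels.
#' @export
simulate_counts <- function(config, truth = simulate_ground_truth(config)) {
  stopifnot(inherits(config, "simulation_config"), inherits(truth, "mg1_truth"))
  set.seed(config$rng_seed + 3L)
  cells <- dplyr::filter(truth$cells, .data$phase %in% c("G2M", "G1"))
  genes <- truth$genes
  t_eff <- ifelse(cells$phase == "G2M", config$g2m_nominal_time,
                  cells$cell_cycle_time)

  # genes x cells matrix of true (capture-free) means
  mean_one_gene <- function(g) {
    if (genes$wave_group[g] %in% c("stable", "low")) {
      rep(genes$m0[g], length(t_eff))
    } else {
      decay_model(t_eff, genes$m0[g], genes$mu[g], genes$gamma[g],
                  genes$t_onset[g])
    }
  }
  mu_mat <- vapply(seq_len(nrow(genes)), mean_one_gene,
                   numeric(length(t_eff)))
  mu_mat <- t(mu_mat)  # genes x cells
  if (any(mu_mat <= 0))
    stop("invalid parameter draw: non-positive model mean for a decaying gene",
         call. = FALSE)

  capture <- cells$capture_efficiency
  if (config$qc_spikeins) {
    expected_total <- colSums(mu_mat)
    lo <- cells$qc_class == "low"
    hi <- cells$qc_class == "high"
    capture[lo] <- runif(sum(lo), config$qc_low_total_range[1],
                         config$qc_low_total_range[2]) / expected_total[lo]
    capture[hi] <- runif(sum(hi), config$qc_high_total_range[1],
                         config$qc_high_total_range[2]) / expected_total[hi]
  }
  mu_mat <- sweep(mu_mat, 2, capture, `*`)

  n <- length(mu_mat)
  if (config$nb_dispersion > 0) {
    counts <- rnbinom(n, size = 1 / config$nb_dispersion, mu = as.vector(mu_mat))
  } else {
    counts <- rpois(n, as.vector(mu_mat))
  }
  m <- matrix(counts, nrow = nrow(genes),
              dimnames = list(genes$gene_id, cells$cell_id))
  counts_matrix(m, plate = setNames(cells$plate_id, cells$cell_id))
}

#' Run the full generator
#'
#' Convenience wrapper producing traces, FACS snapshot, counts, and ground
#' truth from one config.
#'
#' @param config A [simulation_config()].
#' @return A list with `truth`, `traces`, `trace_truth`, `facs`, `counts`.
#' @export
simulate_experiment <- function(config) {
  truth <- simulate_ground_truth(config)
  tr <- simulate_fucci_traces(config)
  facs <- simulate_facs_snapshot(config, truth)
  counts <- simulate_counts(config, truth)
  list(truth = truth, traces = tr$traces, trace_truth = tr$trace_truth,
       facs = facs, counts = counts)
}

#' Write / read ground-truth tables
#'
#' `export_truth()` writes the per-gene and per-cell truth tables as TSV;
#' `read_truth()` reads them back. The round trip reproduces all values.
#'
#' @param truth A [simulate_ground_truth()] result.
#' @param dir Directory to write `gene_truth.tsv` and `cell_truth.tsv` into
#'   (created if needed).
#' @return `export_truth()` the paths written (invisibly); `read_truth()` a
#'   list with tibbles `genes` and `cells`.
#' @export
export_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "mg1_truth"))
  if (!dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("gene_truth.tsv", "cell_truth.tsv"))
  readr::write_tsv(truth$genes, paths[1])
  readr::write_tsv(truth$cells, paths[2])
  invisible(paths)
}

#' @rdname export_truth
#' @export
read_truth <- function(dir) {
  list(genes = readr::read_tsv(file.path(dir, "gene_truth.tsv"),
                               show_col_types = FALSE),
       cells = readr::read_tsv(file.path(dir, "cell_truth.tsv"),
                               show_col_types = FALSE))
}
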