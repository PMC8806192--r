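# End-to-end orchestration: simulate (or load) -> calibrate -> timestamp ->
# QC -> differential expression -> wave detection -> decay fitting ->
# machine-readable report.

#' Build a pipeline run configuration
#'
#' Nested list of per-stage parameters, every default mirroring the study's
#' stated constants (0.31 crosstalk, 5900/111000 UMI bounds, detection mean
#' 2, alpha 0.05, 2-fold cut, -0.95 derivative threshold, onset grid
#' 0-370 step 10). Pass a [simulation_config()] to control the generator, or
#' `inputs` paths to run on supplied files instead.
#'
#' @param simulation A [simulation_config()], or `NULL` to disable the
#'   generator (then `inputs` must supply files).
#' @param inputs Optional list of paths: `traces` (CSV), `facs` (CSV),
#'   `counts_dir` (MTX directory, see [read_counts_mtx()]). Supplied inputs
#'   take precedence over simulation; stages whose inputs are absent are
#'   skipped.
#' @param calibration,qc,de,waves,decay Per-stage parameter overrides
#'   (partial lists merged over defaults).
#' @param rng_seed Seed recorded in the report and used for any simulation
#'   (overrides `simulation$rng_seed`).
#' @return A `run_config` list.
#' @export
run_config <- function(simulation = simulation_config(),
                       inputs = list(),
                       calibration = list(), qc = list(), de = list(),
                       waves = list(), decay = list(),
                       rng_seed = if (!is.null(simulation))
                         simulation$rng_seed else 1L) {
  defaults <- list(
    calibration = list(crosstalk_fraction = 0.31, clip_frac = 0.05,
                       min_coverage = 0.5, confidence_horizon = 300),
    qc = list(umi_lower = 5900, umi_upper = 111000, min_mean = 2,
              sf_method = "libsize"),
    de = list(alpha = 0.05, fold_cut = 2, g1_horizon = 240,
              test = "nb", pseudocount = 0.1),
    waves = list(threshold = -0.95, mode = "window", boundary = 45,
                 grid_step = 1, grid_end = 540),
    decay = list(grid_start = 0, grid_end = 370, grid_step = 10,
                 g2m_nominal_time = -10, gamma_lower = 1e-5,
                 gamma_upper = 1))
  merge1 <- function(base, user) {
    for (nm in names(user)) base[[nm]] <- user[[nm]]
    base
  }
  cfg <- list(simulation = simulation, inputs = inputs,
              calibration = merge1(defaults$calibration, calibration),
              qc = merge1(defaults$qc, qc),
              de = merge1(defaults$de, de),
              waves = merge1(defaults$waves, waves),
              decay = merge1(defaults$decay, decay),
              rng_seed = as.integer(rng_seed))
  if (!is.null(cfg$simulation)) cfg$simulation$rng_seed <- cfg$rng_seed
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys `simulation`, `calibration`, `qc`, `de`, `waves`, `decay`,
#' `inputs`, `rng_seed`; each a mapping of the corresponding [run_config()]
#' arguments.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$simulation)) do.call(simulation_config, y$simulation)
         else simulation_config()
  run_config(simulation = sim,
             inputs = y$inputs %||% list(),
             calibration = y$calibration %||% list(),
             qc = y$qc %||% list(), de = y$de %||% list(),
             waves = y$waves %||% list(), decay = y$decay %||% list(),
             rng_seed = y$rng_seed %||% sim$rng_seed)
}

# lightweight numeric fingerprint for report provenance
fingerprint <- function(x) {
  v <- suppressWarnings(as.numeric(x))
  v <- v[is.finite(v)]
  if (length(v) == 0) return(0)
  round(sum(v) %% 1e9, 6)
}

#' Run the full pipeline
#'
#' Executes simulate -> calibrate -> timestamp -> QC -> DE -> waves ->
#' decay fitting in order, skipping downstream stages when their inputs are
#' unavailable (e.g. FACS but no counts runs only calibration and
#' timestamping). Identical config and seed give identical results.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, stage tables (timed cells,
#'   DE table, wave calls, decay fits) and the report JSON are written
#'   there.
#' @return A `run_report` list (see [write_report()]); stage result objects
#'   are attached in its `results` element.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  report <- list(rng_seed = config$rng_seed,
                 parameters = config[c("calibration", "qc", "de",
                                       "waves", "decay")],
                 stages = list())
  results <- list()
  truth <- NULL

  # --- inputs: simulate or load -------------------------------------------
  traces <- facs <- counts <- NULL
  if (!is.null(config$inputs$traces))
    traces <- readr::read_csv(config$inputs$traces, show_col_types = FALSE)
  if (!is.null(config$inputs$facs))
    facs <- readr::read_csv(config$inputs$facs, show_col_types = FALSE)
  if (!is.null(config$inputs$counts_dir))
    counts <- read_counts_mtx(config$inputs$counts_dir)
  if (!is.null(config$simulation)) {
    sim <- simulate_experiment(config$simulation)
    truth <- sim$truth
    if (is.null(traces)) traces <- sim$traces
    if (is.null(facs)) facs <- sim$facs
    if (is.null(counts)) counts <- sim$counts
    results$truth <- truth
  }
  if (is.null(traces))
    stop("stage calibrate: no traces supplied or simulated", call. = FALSE)

  # --- calibrate -----------------------------------------------------------
  cal_p <- config$calibration
  curve <- tryCatch(
    fit_fucci_calibration(traces,
                          crosstalk_fraction = cal_p$crosstalk_fraction,
                          clip_frac = cal_p$clip_frac,
                          min_coverage = cal_p$min_coverage),
    error = function(e) stop("stage calibrate: ", conditionMessage(e),
                             call. = FALSE))
  results$calibration <- curve
  report$stages$calibrate <- list(
    n_traces = curve$n_traces,
    valid_time_range = curve$valid_time_range,
    coefficients = curve$coefficients,
    early_s_mean_traces = curve$early_s_mean,
    median_timing_sd = median(curve$timing_sd_table$timing_sd),
    input_fingerprint = fingerprint(traces$g1))

  # --- timestamp -----------------------------------------------------------
  timed <- NULL
  if (!is.null(facs)) {
    timed <- tryCatch(
      assign_times(facs, curve,
                   crosstalk_fraction = cal_p$crosstalk_fraction,
                   confidence_horizon = cal_p$confidence_horizon),
      error = function(e) stop("stage timestamp: ", conditionMessage(e),
                               call. = FALSE))
    results$timed_cells <- timed
    report$stages$timestamp <- list(
      n_cells = nrow(timed),
      n_g1_timed = sum(!is.na(timed$cell_cycle_time)),
      n_low_confidence = sum(timed$time_flag == "low_confidence",
                             na.rm = TRUE),
      early_s_mean_facs = attr(timed, "early_s_mean"),
      input_fingerprint = fingerprint(facs$g1_raw))
  }

  if (is.null(counts) || is.null(timed)) {
    report$results <- results
    class(report) <- "run_report"
    if (!is.null(out_dir)) write_pipeline_outputs(report, out_dir)
    return(report)
  }

  # --- qc ------------------------------------------------------------------
  qc_p <- config$qc
  kept <- tryCatch({
    f <- filter_cells_by_umi(counts, qc_p$umi_lower, qc_p$umi_upper)
    compute_size_factors(f, method = qc_p$sf_method)
  }, error = function(e) stop("stage qc: ", conditionMessage(e),
                              call. = FALSE))
  qs <- qc_summary(kept)
  timed_kept <- dplyr::filter(timed, .data$cell_id %in% colnames(kept$counts))
  g2m_cells <- timed_kept$cell_id[timed_kept$gate_label == "G2M"]
  detected <- tryCatch(
    filter_detected_genes(kept, g2m_cells, min_mean = qc_p$min_mean),
    error = function(e) stop("stage qc: ", conditionMessage(e),
                             call. = FALSE))
  results$counts_qc <- kept
  results$detected_genes <- detected
  report$stages$qc <- list(
    n_cells_input = qs$n_input, n_cells_kept = qs$n_kept,
    n_removed_low = qs$n_removed_low, n_removed_high = qs$n_removed_high,
    umi_bounds = c(qs$lower, qs$upper),
    n_genes_input = nrow(kept$counts),
    n_genes_detected = length(detected),
    size_factor_method = qc_p$sf_method,
    input_fingerprint = fingerprint(umi_totals(counts)))

  # --- differential expression --------------------------------------------
  de_p <- config$de
  de_tbl <- tryCatch({
    part <- select_de_cells(timed_kept, g1_horizon = de_p$g1_horizon)
    thr <- bonferroni_threshold(de_p$alpha, length(detected))
    test_differential_expression(kept, part, genes = detected,
                                 test = de_p$test,
                                 pseudocount = de_p$pseudocount) |>
      classify_de_genes(fold_cut = de_p$fold_cut, threshold = thr)
  }, error = function(e) stop("stage de: ", conditionMessage(e),
                              call. = FALSE))
  results$de <- de_tbl
  thr <- bonferroni_threshold(de_p$alpha, length(detected))
  report$stages$de <- list(
    n_tested = nrow(de_tbl),
    bonferroni_threshold = thr,
    n_down = sum(de_tbl$direction == "down"),
    n_up = sum(de_tbl$direction == "up"),
    n_ns = sum(de_tbl$direction == "ns"))

  down_genes <- de_tbl$gene_id[de_tbl$direction == "down"]

  # cell times for modeling: full G1 set plus G2/M at the nominal
  # pre-metaphase time
  dec_p <- config$decay
  times <- setNames(timed_kept$cell_cycle_time, timed_kept$cell_id)
  times[timed_kept$gate_label == "G2M"] <- dec_p$g2m_nominal_time

  # --- waves ---------------------------------------------------------------
  wav_p <- config$waves
  wave_tbl <- NULL
  if (length(down_genes) > 0) {
    wave_tbl <- tryCatch(
      call_waves(kept, times, down_genes, grid_step = wav_p$grid_step,
                 grid_end = wav_p$grid_end, threshold = wav_p$threshold,
                 mode = wav_p$mode, boundary = wav_p$boundary),
      error = function(e) stop("stage waves: ", conditionMessage(e),
                               call. = FALSE))
    results$waves <- wave_tbl
    report$stages$waves <- list(
      n_genes = nrow(wave_tbl),
      n_immediate = sum(wave_tbl$wave_group == "immediate"),
      n_delayed = sum(wave_tbl$wave_group == "delayed"),
      n_degenerate = sum(wave_tbl$wave_group == "degenerate"))
  }

  # --- decay fitting -------------------------------------------------------
  if (length(down_genes) > 0) {
    grid <- seq(dec_p$grid_start, dec_p$grid_end, by = dec_p$grid_step)
    fits <- tryCatch(
      fit_decay_genes(kept, times, down_genes, onset_grid = grid,
                      gamma_bounds = c(dec_p$gamma_lower,
                                       dec_p$gamma_upper)),
      error = function(e) stop("stage fit-decay: ", conditionMessage(e),
                               call. = FALSE))
    results$decay <- fits
    summ <- summarize_fits(fits, wave_tbl)
    results$decay_summary <- summ
    report$stages$decay <- list(
      n_genes = summ$n_genes, n_converged = summ$n_converged,
      n_decaying = summ$n_decaying,
      median_half_life = summ$median_half_life,
      onset_grid = c(dec_p$grid_start, dec_p$grid_end, dec_p$grid_step))
  }

  report$results <- results
  class(report) <- "run_report"
  if (!is.null(out_dir)) write_pipeline_outputs(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> seed", x$rng_seed, "\n")
  for (nm in names(x$stages)) {
    s <- x$stages[[nm]]
    nums <- vapply(s, function(v) length(v) == 1 && is.numeric(v), logical(1))
    cat("  ", nm, ": ",
        paste(names(s)[nums], signif(unlist(s[nums]), 5),
              sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

write_pipeline_outputs <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  r <- report$results
  if (!is.null(r$timed_cells))
    readr::write_csv(r$timed_cells, file.path(out_dir, "timed_cells.csv"))
  if (!is.null(r$de))
    readr::write_tsv(r$de, file.path(out_dir, "de_table.tsv"))
  if (!is.null(r$waves))
    readr::write_tsv(r$waves, file.path(out_dir, "wave_calls.tsv"))
  if (!is.null(r$decay))
    readr::write_tsv(r$decay, file.path(out_dir, "decay_fits.tsv"))
  write_report(report, file.path(out_dir, "report.json"))
  invisible(out_dir)
}

#' Write / read / validate a run report
#'
#' `write_report()` serializes the numeric part of a `run_report` (seed,
#' parameters, per-stage counts) as JSON; stage result objects are not
#' serialized. `read_report()` reads it back and validates the schema,
#' including filter conservation (kept + removed = input).
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param path JSON file path.
#' @return `write_report()` the path, invisibly; `read_report()` the report
#'   list.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  out <- report[c("rng_seed", "parameters", "stages")]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  rep <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  required <- c("rng_seed", "parameters", "stages")
  missing <- setdiff(required, names(rep))
  if (length(missing) > 0)
    stop("invalid report: missing ", paste(missing, collapse = ", "),
         call. = FALSE)
  qc <- rep$stages$qc
  if (!is.null(qc)) {
    if (qc$n_cells_kept + qc$n_removed_low + qc$n_removed_high !=
          qc$n_cells_input)
      stop("invalid report: QC cell counts do not conserve", call. = FALSE)
  }
  de <- rep$stages$de
  if (!is.null(de) && de$n_down + de$n_up + de$n_ns != de$n_tested)
    stop("invalid report: DE counts do not conserve", call. = FALSE)
  rep
}
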