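# Shared fixtures: a fast, small-scale simulation config for unit tests.
# Expression totals at this scale are ~3k UMIs, so tests that exercise the
# UMI filter pass bounds appropriate to the scale (the study-scale defaults
# are exercised in the acceptance tests).

small_sim_config <- function(seed = 42, ...) {
  defaults <- list(
    n_g2m_cells = 30L, n_g1_cells = 200L, n_early_s_cells = 25L,
    n_genes_immediate = 12L, n_genes_delayed = 12L, n_genes_stable = 120L,
    n_genes_low = 4L, n_traces = 30L,
    n_qc_low = 5L, n_qc_high = 3L,
    qc_low_total_range = c(50, 200),
    qc_high_total_range = c(40000, 60000),
    rng_seed = seed)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

small_umi_bounds <- c(lower = 500, upper = 20000)

# per-cell model-time vector (G2/M at the nominal pre-metaphase time)
truth_times <- function(truth, cm, g2m_time = -10) {
  cells <- truth$cells[truth$cells$cell_id %in% colnames(cm$counts), ]
  setNames(ifelse(cells$phase == "G2M", g2m_time, cells$cell_cycle_time),
           cells$cell_id)
}

# tiny counts_matrix from explicit totals, one gene per matrix row
totals_matrix <- function(totals, n_plates = 1) {
  m <- matrix(as.integer(totals), nrow = 1,
              dimnames = list("G1", sprintf("c%d", seq_along(totals))))
  counts_matrix(m, plate = rep(sprintf("plate%d", seq_len(n_plates)),
                               length.out = length(totals)))
}
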