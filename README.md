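# mg1kinetics

Time-resolved mRNA decay kinetics at the mitosis-to-G1 transition, from
FUCCI-calibrated single-cell RNA-seq.

When cells exit mitosis, a large cohort of cell-cycle mRNAs is actively
degraded in two waves — one at mitotic exit, one in early G1. This package
is for researchers who profile FUCCI reporter lines with plate-based
single-cell RNA-seq (SORT-seq / CEL-Seq2) and want absolute-time kinetics
out of it. It provides:

* **FUCCI time calibration** — fit the mean live-cell FUCCI-G1 trace to a
  monotone third-order polynomial (early-S-phase normalized, 31%
  G1-to-G2 channel crosstalk corrected), then invert it to assign each
  FACS-sorted cell a time in minutes since metaphase, with per-time
  uncertainty (SD of FUCCI-G1 timing).
* **SORT-seq quality control** — UMI-total bounds (5,900–111,000),
  library-size factors for per-cell mRNA recovery, and a plate-wise
  detection filter (mean ≥ 2 raw counts over G2/M cells in every plate).
* **Differential expression** — negative-binomial GLM likelihood-ratio
  test of G2/M versus early-G1 cells with 2-fold and Bonferroni
  (`0.05 / n_genes`) cutoffs.
* **Decline-wave detection** — GCV smoothing splines of expression versus
  time; the time of steepest decline and the first −0.95 crossing of the
  min-normalized derivative classify genes into *immediate* and *delayed*
  waves.
* **Two-phase decay model** — per gene,
  `dm/dt = mu − gamma·m` with constant `m0` before an onset time:
  `m(t) = mu/gamma + (m0 − mu/gamma)·exp(−gamma·(t − t_onset))` for
  `t ≥ t_onset`. Fit by grid search over `t_onset` (0–370 min, step 10)
  with bounded least squares over `(m0, mu, gamma)`;
  half-life = `ln 2 / gamma`.
* **A seeded synthetic-data generator** with full ground truth (traces,
  FACS snapshot, NB counts with planted kinetics), so every stage is
  testable without any external data.

## Worked example

```r
library(mg1kinetics)

cfg    <- simulation_config(rng_seed = 1)   # study-scale synthetic cohort
report <- run_pipeline(run_config(cfg))
report
#> <run_report> seed 1
#>   calibrate: n_traces=90, early_s_mean_traces=192.59, median_timing_sd=58.201, ...
#>   timestamp: n_cells=945, n_g1_timed=785, n_low_confidence=284, early_s_mean_facs=190.12, ...
#>   qc: n_cells_input=885, n_cells_kept=855, n_removed_low=20, n_removed_high=10,
#>       n_genes_input=2130, n_genes_detected=2105, ...
#>   de: n_tested=2105, bonferroni_threshold=2.3753e-05, n_down=52, n_up=0, n_ns=2053
#>   waves: n_genes=52, n_immediate=45, n_delayed=7, n_degenerate=0
#>   decay: n_genes=52, n_converged=52, n_decaying=52, median_half_life=52.54
```

Reading this: 90 simulated live-cell traces calibrate the FUCCI curve
(early-S mean intensity 192.6); 785 G1-gated cells receive times, 284 of
them beyond the 300-min confidence horizon. QC drops exactly the 30
planted out-of-bounds cells (20 low, 10 high) from 885 sequenced cells;
2,105 genes pass the plate-wise detection filter, so the Bonferroni
threshold is 0.05 / 2105 = 2.38e-5. 52 genes are called down in G1 (≥
2-fold, significant), split 45 immediate / 7 delayed by the spline
derivative rule, and their fitted half-lives have median 52.5 min.

Per-gene results are tidy tibbles:

```r
fits <- report$results$decay
dplyr::arrange(fits, sse)[1:3, c("gene_id", "m0", "gamma", "t_onset", "half_life")]
#> # A tibble: 3 × 5
#>   gene_id     m0   gamma t_onset half_life
#>   <chr>    <dbl>   <dbl>   <dbl>     <dbl>
#> 1 GENE0021  3.53 0.00953       0      72.7
#> 2 GENE0030  4.77 0.0135        0      51.4
#> 3 GENE0035  4.80 0.0134        0      51.7

summarize_fits(fits, report$results$waves)
#> <decay_summary> 52 decaying / 52 converged / 52 genes
#>   median half-life: 52.54 min
#> # A tibble: 2 × 4
#>   wave_group     n median_half_life median_t_onset
#>   <chr>      <int>            <dbl>          <dbl>
#> 1 delayed        7             46.2             30
#> 2 immediate     45             56.8             10
```

Individual stages compose with the pipe — e.g.
`simulate_counts(cfg) |> filter_cells_by_umi() |> compute_size_factors()`
— and fitted objects have `tidy()`, `glance()`, and `autoplot()` methods
(`autoplot(calibration)`, `autoplot(single_gene_fit)`,
`plot_onset_histogram(fits)`, `plot_wave_calls(waves)`).

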