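# Independent brute-force oracle for the decay fit: exhaustive evaluation of
# the two-phase model SSE over a dense 4-parameter lattice
# (t_onset x gamma x m0 x steady-state), reparametrized as
# m(t) = ss + (m0 - ss) * E(t) with E = 1 before onset and
# exp(-gamma (t - onset)) after, so the SSE is evaluated in closed form for
# every lattice point. No shared code with fit_decay().

oracle_lattice_fit <- function(times, expr,
                               onset_grid = seq(0, 370, by = 10),
                               gamma_grid, m0_grid, ss_grid) {
  sy2 <- sum(expr^2)
  best <- list(sse = Inf, t_onset = NA_real_)
  for (on in onset_grid) {
    for (g in gamma_grid) {
      E <- ifelse(times < on, 1, exp(-g * (times - on)))
      one_m_E <- 1 - E
      sEE <- sum(E * E); sE1 <- sum(E * one_m_E); s11 <- sum(one_m_E^2)
      syE <- sum(expr * E); sy1 <- sum(expr * one_m_E)
      for (m0 in m0_grid) {
        sse <- sy2 - 2 * m0 * syE - 2 * ss_grid * sy1 + m0^2 * sEE +
          2 * m0 * ss_grid * sE1 + ss_grid^2 * s11
        i <- which.min(sse)
        if (sse[i] < best$sse)
          best <- list(sse = sse[i], t_onset = on, gamma = g, m0 = m0,
                       ss = ss_grid[i])
      }
    }
  }
  best
}
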