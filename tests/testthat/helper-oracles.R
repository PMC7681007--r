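# Independent oracles and shared fixtures for the suite.

# Free-antibody oracle: dense grid scan for the sign change of the
# conservation defect, refined with stats::uniroot. Independent of the
# package's bisection path.
oracle_free_antibody <- function(antibody_total, totals, K,
                                 n_grid = 20000L) {
  g <- function(a) a + sum(totals * a * K / (1 + a * K)) - antibody_total
  if (antibody_total == 0 || sum(totals * K) == 0) return(antibody_total)
  grid <- seq(0, antibody_total, length.out = n_grid)
  vals <- vapply(grid, g, numeric(1))
  i <- which(vals >= 0)[1L]
  if (i == 1L) return(0)
  stats::uniroot(g, c(grid[i - 1L], grid[i]), tol = 1e-14)$root
}

# Hypergeometric upper-tail oracle by exhaustive enumeration of all
# C(N, nB) draws of B-bins from the universe; feasible for N <= 12.
oracle_hyper_p <- function(N, nA, nB, observed) {
  draws <- utils::combn(N, nB)
  hits <- colSums(draws <= nA)   # WLOG A occupies bins 1..nA
  mean(hits >= observed)
}

# The four-species depletion reaction used across isotherm tests (target,
# weak off-target, 22-fold off-target), antibody 6 uM.
legend_reaction <- function(s1t = 10.4, s2t = 0.3, s3t = 0.3,
                            spikes = FALSE) {
  sp <- rbind(species("target", s1t, 11),
              species("off1", s2t, 0.1),
              species("off2", s3t, 0.5))
  if (spikes) {
    sp <- rbind(sp,
                species("spike_t", 0.03, 11, spike = TRUE),
                species("spike_o", 0.03, 0.5, spike = TRUE))
  }
  reaction(6, sp)
}

# Paper-worked IP manifest (input side is only needed structurally in some
# tests; callers override fields as needed).
worked_ip_manifest <- function() {
  sample_manifest(mapped_reads = 37298373,
                  library_sequenced = 20, library_total = 856,
                  pcr_cycles = 11, bead_capture_yield = 1,
                  ip_mass_total = 24.2, mass_into_library = 10)
}

# A three-species synthetic scenario with partially overlapping genomic
# distributions on the default toy genome; the study conditions for the
# pipeline-recovery checks.
recovery_scenario <- function() {
  g <- toy_genome()                       # 2 x 1 Mb, 10 kb intervals
  nb <- nrow(g)                           # 200 intervals
  o <- matrix(0, 3, nb,
              dimnames = list(c("target", "off1", "off2"), NULL))
  o["target", 1:80] <- 1 / 80
  o["off1", 85:140] <- 1 / 56
  o["off2", 120:200] <- 1 / 81
  list(reaction = legend_reaction(), distributions = o, genome = g)
}

# Recover the 1D efficiency track from a generated experiment and return the
# mean absolute error against the ledger's expected efficiency, over
# intervals the input distribution actually populates.
recovered_mae <- function(gen) {
  al <- compute_alpha(gen$manifest$ip, gen$manifest$input,
                      gen$manifest$volumes)
  tr <- efficiency_track(gen$ip, gen$input, al,
                         interval_width = gen$ledger$interval_width)
  led <- gen$ledger$expected_efficiency
  m <- merge(as.data.frame(tr)[, c("chrom", "xbin", "value")], led,
             by = c("chrom", "xbin"), all.y = TRUE)
  m$value[is.na(m$value)] <- 0
  keep <- gen$ledger$p_input > 0
  mean(abs(m$value - m$efficiency)[keep])
}
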