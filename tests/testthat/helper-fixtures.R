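# Shared fixture builders for the test suite. All data are generated in
# code; seeds are fixed by the callers.

ref_genotype <- function(id = "Col FRI", S = 10, r1 = 0.2, r2 = 0.3, ...) {
  genotype_params(id, starting_level = S, rate_vindep = r1, rate_vdep = r2,
                  ...)
}

# A small two-phase field season: breakpoint at day 48, 4 timepoints per
# phase, weekly-ish sampling.
two_phase_config <- function(genotypes = list(ref_genotype()),
                             noise_sd_log = 0.2, block_sd_log = 0,
                             seed = 1, ...) {
  simulation_config(genotypes,
                    timepoints = c(20, 27, 34, 41, 55, 62, 69, 76),
                    breakpoint_day = 48, noise_sd_log = noise_sd_log,
                    block_sd_log = block_sd_log, seed = seed, ...)
}

# qPCR fixture: n samples of one genotype/day, technical duplicates for
# FLC and UBC, well-behaved unless perturbed by the caller.
qpcr_fixture <- function(n = 6, flc_cq = 26, ubc_cq = 22) {
  do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(sample_id = sprintf("s%02d", i), genotype = "Col FRI",
               day = 20, amplicon = rep(c("FLC", "UBC"), each = 2),
               technical_rep = rep(1:2, 2),
               cq = c(flc_cq, flc_cq + 0.1, ubc_cq, ubc_cq + 0.1),
               retest = FALSE, stringsAsFactors = FALSE)
  }))
}

expect_identical_tables <- function(a, b) {
  expect_identical(a, b)
}
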