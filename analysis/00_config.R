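# Shared configuration for the numbered analysis drivers.
# Every driver regenerates what it needs from this config; the generator is
# deterministic, so stages agree without passing R objects between scripts.

library(gutvirome)

ANALYSIS_SEED <- 20260930L %% 2147483647L
FIXTURE_DIR <- "results/fixtures"
RESULTS_DIR <- "results"

# Full study-design cohort for the statistical stages.
cohort_config <- function() {
  sim_config(seed = ANALYSIS_SEED, n_bacterial_clades = 50L)
}

# Compact sequence bundle for the contig-level stages (identification,
# taxonomy, quantification, CRISPR): 40 viral + 12 bacterial contigs over
# 6 synthetic samples keeps every stage under a few seconds.
sequence_config <- function() {
  sim_config(seed = ANALYSIS_SEED, n_viral_contigs = 40L,
             n_bacterial_contigs = 12L, n_bacterial_clades = 0L)
}

dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)
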