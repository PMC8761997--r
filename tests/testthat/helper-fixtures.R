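# Shared fixture builders for the test suite.  All fixtures are generated in
# code; nothing is read from disk.

no_effects <- function() {
  data.frame(clade = character(0), disease = character(0),
             effect = numeric(0), stringsAsFactors = FALSE)
}

no_pairs <- function() {
  data.frame(viral_clade = character(0), bacterial_clade = character(0),
             rho = numeric(0), stringsAsFactors = FALSE)
}

# Full-cohort config (476 samples, study design) with only the viral block,
# used by the statistical calibration tests.
null_cohort_config <- function(seed, ...) {
  sim_config(seed = seed, n_bacterial_clades = 0L,
             planted_effects = no_effects(),
             coabundance_pairs = no_pairs(), ...)
}

effect_cohort_config <- function(seed, effect, ...) {
  sim_config(seed = seed, n_bacterial_clades = 0L,
             planted_effects = data.frame(
               clade = "crAss-like phage",
               disease = c("RA", "SLE", "MS"),
               effect = effect, stringsAsFactors = FALSE),
             coabundance_pairs = no_pairs(), ...)
}

# Small contig/cohort config for fast structural tests.
small_config <- function(seed = 7, ...) {
  sim_config(seed = seed,
             n_samples_per_group = c(HC = 40L, RA = 16L, SLE = 8L, MS = 6L),
             n_viral_contigs = 10L, n_bacterial_contigs = 5L,
             n_bacterial_clades = 10L, ...)
}

# Hand-built metadata for direct model tests (no generator involved).
toy_metadata <- function(n, phenotype, seed = 1) {
  set.seed(seed)
  data.frame(
    sample_id = sprintf("T%03d", seq_len(n)),
    phenotype = phenotype,
    age = round(runif(n, 25, 80), 1),
    sex = sample(c("male", "female"), n, TRUE),
    batch = sample(1:2, n, TRUE),
    total_bases = runif(n, 5e9, 9e9),
    antibiotics = FALSE, ppi = FALSE, steroid = FALSE,
    treated = phenotype != "HC" & runif(n) < 0.5,
    new_onset = phenotype != "HC" & runif(n) < 0.5,
    activity_score = ifelse(phenotype != "HC", rnorm(n, 3, 1), NA_real_),
    marker = rlnorm(n, 0, 0.5),
    stringsAsFactors = FALSE)
}

# Deterministic planted CRISPR contig: three exact repeat copies with
# disagreeing flanking columns so repeat extension stops exactly at the
# planted boundaries.
planted_crispr_contig <- function(seed = 11, repeat_len = 30L,
                                  spacer_lens = c(32L, 34L),
                                  contig_len = 6000L) {
  set.seed(seed)
  rnd <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = "")
  rep_seq <- rnd(repeat_len)
  sp1 <- paste0("T", rnd(spacer_lens[1] - 2L), "A")
  sp2 <- paste0("G", rnd(spacer_lens[2] - 2L), "C")
  left <- paste0(rnd(2000L - 1L), "G")   # column left of repeat 1
  right <- paste0("A", rnd(contig_len - 2000L - repeat_len * 3L -
                           sum(spacer_lens) - 1L))
  arr <- paste0(rep_seq, sp1, rep_seq, sp2, rep_seq)
  list(sequence = paste0(left, arr, right),
       repeat_seq = rep_seq,
       spacers = c(sp1, sp2),
       array_start = 2001L,
       array_end = 2000L + nchar(arr))
}
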