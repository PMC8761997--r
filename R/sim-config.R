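#' Simulation configuration for the synthetic cohort
#'
#' Bundles every knob of the synthetic-data generator into one validated
#' object.  Defaults mirror the study design the package re-analyses: a
#' 476-sample cohort (289 healthy controls, 111 rheumatoid arthritis, 47
#' systemic lupus erythematosus, 29 multiple sclerosis) sequenced in five
#' batches, with disease effects planted on the crAss-like phage and
#' *Podoviridae* families and a *Podoviridae*--*Faecalibacterium*
#' co-abundance.
#'
#' @param seed Master seed; every generator component derives its own
#'   stream from it, so identical configs give byte-identical fixtures.
#' @param n_samples_per_group Named integer vector of cohort sizes.
#' @param n_viral_contigs,n_bacterial_contigs Contig counts for the sequence
#'   fixtures.
#' @param circular_fraction Fraction of viral contigs built circular (exact
#'   terminal repeat).
#' @param terminal_overlap Length in bp of the exact terminal repeat carried
#'   by circular contigs (the detection rule requires >= 50).
#' @param planted_effects Data frame with columns `clade`, `disease`,
#'   `effect`: per-standard-deviation log-odds shifts planted on case
#'   samples' log abundance.
#' @param coabundance_pairs Data frame with columns `viral_clade`,
#'   `bacterial_clade`, `rho`: log-scale noise correlations, each strictly
#'   inside (-1, 1).
#' @param batch_count Number of sequencing batches (the design tables assume
#'   5).
#' @param noise_sd Residual SD of log10 abundance.
#' @param batch_sd SD of per-clade batch offsets.
#' @param zero_inflation Probability an abundance entry is set to absent.
#' @param n_bacterial_clades Number of synthetic bacterial species-level
#'   clades in the cohort abundance fixture.
#' @param age_effect,sex_effect Optional per-year / female-indicator shifts
#'   of log10 abundance (defaults 0: the study found no age/sex signal).
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_samples_per_group = c(HC = 289L, RA = 111L,
                                               SLE = 47L, MS = 29L),
                       n_viral_contigs = 30L,
                       n_bacterial_contigs = 10L,
                       circular_fraction = 0.3,
                       terminal_overlap = 55L,
                       planted_effects = default_planted_effects(),
                       coabundance_pairs = default_coabundance_pairs(),
                       batch_count = 5L,
                       noise_sd = 1,
                       batch_sd = 0.3,
                       zero_inflation = 0.05,
                       n_bacterial_clades = 50L,
                       age_effect = 0,
                       sex_effect = 0) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (any(n_samples_per_group < 0) || any(n_viral_contigs < 0) ||
      any(n_bacterial_contigs < 0) || n_bacterial_clades < 0) {
    stop("all counts must be >= 0", call. = FALSE)
  }
  if (is.null(names(n_samples_per_group)) ||
      any(!nzchar(names(n_samples_per_group)))) {
    stop("n_samples_per_group must be a named vector", call. = FALSE)
  }
  if (circular_fraction < 0 || circular_fraction > 1) {
    stop("circular_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  if (zero_inflation < 0 || zero_inflation >= 1) {
    stop("zero_inflation must lie in [0, 1)", call. = FALSE)
  }
  if (nrow(coabundance_pairs) &&
      any(abs(coabundance_pairs$rho) >= 1)) {
    stop("coabundance correlations must be strictly inside (-1, 1)",
         call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed),
         n_samples_per_group = n_samples_per_group,
         n_viral_contigs = as.integer(n_viral_contigs),
         n_bacterial_contigs = as.integer(n_bacterial_contigs),
         circular_fraction = circular_fraction,
         terminal_overlap = as.integer(terminal_overlap),
         planted_effects = planted_effects,
         coabundance_pairs = coabundance_pairs,
         batch_count = as.integer(batch_count),
         noise_sd = noise_sd,
         batch_sd = batch_sd,
         zero_inflation = zero_inflation,
         n_bacterial_clades = as.integer(n_bacterial_clades),
         age_effect = age_effect,
         sex_effect = sex_effect),
    class = "sim_config")
}

#' The eight viral families retained by clade QC in the study
#' @return Character vector of family names.
#' @export
viral_family_names <- function() {
  c("Autographiviridae", "crAss-like phage", "Herelleviridae",
    "Microviridae", "Myoviridae", "Phycodnaviridae", "Podoviridae",
    "Siphoviridae")
}

#' Default planted case-control effects
#'
#' The significant per-SD effects the original analysis reported: crAss-like
#' phage depletion in RA and SLE and *Podoviridae* depletion in SLE.
#' @return Data frame with columns clade, disease, effect.
#' @export
default_planted_effects <- function() {
  data.frame(
    clade   = c("crAss-like phage", "crAss-like phage", "Podoviridae"),
    disease = c("RA", "SLE", "SLE"),
    effect  = c(-0.476, -0.514, -0.947),
    stringsAsFactors = FALSE)
}

#' Default planted virus-bacterium co-abundance
#' @return Data frame with columns viral_clade, bacterial_clade, rho.
#' @export
default_coabundance_pairs <- function() {
  data.frame(
    viral_clade = "Podoviridae",
    bacterial_clade = "Faecalibacterium_spp",
    rho = 0.35,
    stringsAsFactors = FALSE)
}

# Derive a component-specific 31-bit seed from the master seed so that each
# fixture component owns an independent stream and adding components does not
# perturb earlier ones.
component_seed <- function(seed, component) {
  h <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)))
  as.integer((as.double(seed) * 48271 + h * 16807) %% 2147483647)
}

with_component_seed <- function(seed, component, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(component_seed(seed, component))
  expr
}
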