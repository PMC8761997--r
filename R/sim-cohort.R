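#' Generate cohort metadata and abundance matrices with planted structure
#'
#' Emulates the statistical structure assumed by the downstream association
#' models.  Per-sample per-clade log10 abundance is
#' `baseline + sum(planted disease effect x disease indicator) x noise_sd +
#' batch offset + age/sex nuisance terms + Gaussian noise`, so a planted
#' effect is expressed in residual-SD units and the case-control logistic
#' regression on the standardized abundance recovers it as a per-SD
#' log-odds coefficient.  Co-abundant virus-bacterium pairs share bivariate
#' Gaussian noise with the configured correlation.  A configurable
#' zero-inflation rate sets entries to absent (0 on the raw scale).
#'
#' @param config A [sim_config()].
#' @return List with `viral` (samples x 8 families, raw normalized scale),
#'   `bacterial` (samples x species clades, or NULL when
#'   `n_bacterial_clades == 0`), and `metadata` (sample_id, phenotype, age,
#'   sex, batch, total_bases, medication/onset flags, activity score,
#'   inflammation marker).
#' @export
generate_cohort_abundance <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  metadata <- with_component_seed(config$seed, "metadata",
                                  generate_metadata(config))
  n <- nrow(metadata)
  vfams <- viral_family_names()
  bclades <- if (config$n_bacterial_clades > 0) {
    c("Faecalibacterium_spp",
      if (config$n_bacterial_clades > 1)
        sprintf("Bacterium_%03d", 2:config$n_bacterial_clades))
  } else character(0)

  pe <- config$planted_effects
  if (nrow(pe) && !all(pe$clade %in% vfams)) {
    stop("planted effect clade not among viral families", call. = FALSE)
  }
  cp <- config$coabundance_pairs
  if (nrow(cp) && length(bclades) &&
      !all(cp$bacterial_clade %in% bclades & cp$viral_clade %in% vfams)) {
    stop("coabundance pair references unknown clade", call. = FALSE)
  }
  if (!length(bclades)) cp <- cp[0, , drop = FALSE]

  with_component_seed(config$seed, "abundance", {
    # fixed family baselines on the log10 normalized-depth scale, crAss-like
    # and Siphoviridae most abundant as in real gut viromes
    vbase <- stats::setNames(
      c(-8.5, -7.0, -8.8, -8.2, -7.5, -8.6, -8.0, -7.2), vfams)
    bbase <- if (length(bclades)) {
      stats::setNames(seq(-2, -5, length.out = length(bclades)), bclades)
    } else numeric(0)

    clades <- c(vfams, bclades)
    base <- c(vbase, bbase)
    p <- length(clades)
    batch_off <- matrix(stats::rnorm(config$batch_count * p,
                                     sd = config$batch_sd),
                        nrow = config$batch_count, ncol = p,
                        dimnames = list(NULL, clades))

    # joint noise: independent N(0, noise_sd^2) except configured pairs
    noise <- matrix(stats::rnorm(n * p, sd = config$noise_sd),
                    nrow = n, ncol = p, dimnames = list(NULL, clades))
    if (nrow(cp)) {
      involved <- unique(c(cp$viral_clade, cp$bacterial_clade))
      k <- length(involved)
      sigma <- diag(k) * config$noise_sd^2
      dimnames(sigma) <- list(involved, involved)
      for (i in seq_len(nrow(cp))) {
        v <- cp$viral_clade[i]; b <- cp$bacterial_clade[i]
        sigma[v, b] <- sigma[b, v] <- cp$rho[i] * config$noise_sd^2
      }
      ch <- tryCatch(chol(sigma), error = function(e)
        stop("coabundance correlation matrix not positive definite",
             call. = FALSE))
      z <- matrix(stats::rnorm(n * k), nrow = n, ncol = k) %*% ch
      noise[, involved] <- z
    }

    mu <- matrix(rep(base, each = n), nrow = n, ncol = p,
                 dimnames = list(metadata$sample_id, clades))
    mu <- mu + batch_off[metadata$batch, , drop = FALSE] + noise
    mu <- mu + config$age_effect * (metadata$age - mean(metadata$age))
    mu <- mu + config$sex_effect * (metadata$sex == "female")
    if (nrow(pe)) {
      for (i in seq_len(nrow(pe))) {
        hit <- metadata$phenotype == pe$disease[i]
        mu[hit, pe$clade[i]] <- mu[hit, pe$clade[i]] +
          pe$effect[i] * config$noise_sd
      }
    }

    vals <- 10^mu
    if (config$zero_inflation > 0) {
      drop <- matrix(stats::runif(n * p) < config$zero_inflation,
                     nrow = n, ncol = p)
      vals[drop] <- 0
    }
    viral <- vals[, vfams, drop = FALSE]
    attr(viral, "form") <- "normalized"
    bacterial <- if (length(bclades)) {
      b <- vals[, bclades, drop = FALSE]
      attr(b, "form") <- "normalized"
      b
    } else NULL
    list(viral = viral, bacterial = bacterial, metadata = metadata)
  })
}

# Batch allocation mirroring the study design: RA sequenced in batches 1-3,
# SLE in 2, 3 and 5, MS in batch 4 only, controls spread so the per-disease
# case/control counts match the published design at the default cohort sizes
# (RA 111/111, SLE 47/201, MS 29/74).
design_batch_fractions <- function(batch_count) {
  if (batch_count == 5L) {
    list(HC  = c(14, 48, 49, 74, 104) / 289,
         RA  = c(37, 37, 37, 0, 0) / 111,
         SLE = c(0, 10, 10, 0, 27) / 47,
         MS  = c(0, 0, 0, 29, 0) / 29)
  } else {
    even <- rep(1 / batch_count, batch_count)
    list(HC = even, RA = even, SLE = even, MS = even)
  }
}

# Largest-remainder rounding of n into integer counts proportional to frac.
allocate_counts <- function(n, frac) {
  raw <- n * frac
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

generate_metadata <- function(config) {
  groups <- names(config$n_samples_per_group)
  fracs <- design_batch_fractions(config$batch_count)
  rows <- list()
  for (g in groups) {
    ng <- config$n_samples_per_group[[g]]
    if (ng == 0) next
    fr <- if (g %in% names(fracs)) fracs[[g]] else
      rep(1 / config$batch_count, config$batch_count)
    counts <- allocate_counts(ng, fr)
    rows[[g]] <- data.frame(phenotype = g,
                            batch = rep(seq_len(config$batch_count), counts),
                            stringsAsFactors = FALSE)
  }
  md <- do.call(rbind, rows)
  n <- nrow(md)
  md$sample_id <- sprintf("S%03d", seq_len(n))
  rownames(md) <- NULL

  p_female <- c(HC = 0.5, RA = 0.8, SLE = 0.9, MS = 0.7)
  pf <- ifelse(md$phenotype %in% names(p_female),
               p_female[md$phenotype], 0.5)
  md$sex <- ifelse(stats::runif(n) < pf, "female", "male")
  md$age <- round(pmin(pmax(stats::rnorm(n, 55, 12), 20), 85), 1)
  # batch-wise sequencing yields (Gb) mirror the study's per-batch means
  gb <- c(25.5, 7.8, 6.7, 7.0, 8.3)
  mean_gb <- gb[pmin(md$batch, length(gb))]
  md$total_bases <- stats::rlnorm(n, log(mean_gb * 1e9), 0.15)
  is_case <- md$phenotype != "HC"
  md$antibiotics <- stats::runif(n) < ifelse(is_case, 0.05, 0.02)
  md$ppi <- stats::runif(n) < ifelse(is_case, 0.10, 0.05)
  md$steroid <- stats::runif(n) < ifelse(md$phenotype == "SLE", 0.30,
                                         ifelse(is_case, 0.12, 0.01))
  md$treated <- is_case & stats::runif(n) < 0.8
  md$new_onset <- is_case & stats::runif(n) < 0.3
  md$activity_score <- ifelse(is_case, stats::rnorm(n, 3, 1), NA_real_)
  md$marker <- stats::rlnorm(n, 0, 0.5)
  md[, c("sample_id", "phenotype", "age", "sex", "batch", "total_bases",
         "antibiotics", "ppi", "steroid", "treated", "new_onset",
         "activity_score", "marker")]
}

#' Write a complete synthetic fixture bundle to disk
#'
#' Emits contigs as FASTA, evidence/depth/metadata/abundance tables as
#' tab-separated files with header rows, and the ground truth as its own
#' tab-separated file (never consumed by the pipeline).
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if missing).
#' @param preset Evidence preset passed to [generate_evidence()].
#' @return Invisibly, the list of file paths written.
#' @export
simulate_bundle <- function(config, out_dir, preset = "perfect") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ctg <- generate_contigs(config)
  planted <- plant_crispr_arrays(ctg$bacterial, ctg$viral,
                                 n_arrays = max(1L, config$n_bacterial_contigs %/% 2L),
                                 seed = config$seed)
  ctg$bacterial <- planted$bacterial
  ctg$truth$planted_interactions <- planted$pairs
  ev <- generate_evidence(rbind(ctg$viral, ctg$bacterial), ctg$truth,
                          config, preset = preset)
  tax <- generate_taxonomy_evidence(ctg$viral, ctg$truth)
  dep <- generate_depths(ctg$viral, config)
  coh <- generate_cohort_abundance(config)

  paths <- c(
    viral_fasta = file.path(out_dir, "viral_contigs.fasta"),
    bacterial_fasta = file.path(out_dir, "bacterial_contigs.fasta"),
    evidence = file.path(out_dir, "evidence.tsv"),
    nt_hits = file.path(out_dir, "nt_hits.tsv"),
    taxmap = file.path(out_dir, "taxmap.tsv"),
    depth = file.path(out_dir, "depth.tsv"),
    metadata = file.path(out_dir, "metadata.tsv"),
    viral_abundance = file.path(out_dir, "viral_abundance.tsv"),
    truth = file.path(out_dir, "ground_truth.tsv"))
  write_fasta(stats::setNames(ctg$viral$sequence, ctg$viral$id),
              paths["viral_fasta"])
  write_fasta(stats::setNames(ctg$bacterial$sequence, ctg$bacterial$id),
              paths["bacterial_fasta"])
  write_tsv(ev, paths["evidence"])
  write_tsv(tax$nt_hits, paths["nt_hits"])
  write_tsv(tax$taxmap, paths["taxmap"])
  write_tsv(dep$depth, paths["depth"])
  write_tsv(coh$metadata, paths["metadata"])
  write_matrix_tsv(coh$viral, paths["viral_abundance"])
  truth_df <- data.frame(contig_id = names(ctg$truth$true_taxonomy),
                         family = unname(ctg$truth$true_taxonomy),
                         stringsAsFactors = FALSE)
  write_tsv(truth_df, paths["truth"])
  invisible(paths)
}
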