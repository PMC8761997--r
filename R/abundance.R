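#' Trimmed-mean per-base depth
#'
#' Robust average read depth of a contig: the per-base depths are sorted and
#' the lowest `trim_min` and highest `1 - trim_max` fractions of positions
#' (by rank) are discarded before averaging.  With `trim_min = 0`,
#' `trim_max = 1` this reduces to the arithmetic mean.
#'
#' @param depths Numeric vector of per-base depths (one entry per contig
#'   position, >= 0).
#' @param trim_min,trim_max Rank-fraction bounds (defaults 0.05 and 0.95,
#'   matching the external coverage tool's parameters).
#' @return Numeric scalar.
#' @export
trimmed_mean_depth <- function(depths, trim_min = 0.05, trim_max = 0.95) {
  if (!length(depths)) stop("empty depth vector", call. = FALSE)
  if (any(depths < 0)) stop("depths must be >= 0", call. = FALSE)
  L <- length(depths)
  s <- sort(depths)
  lo <- floor(trim_min * L) + 1L
  hi <- ceiling(trim_max * L)
  if (lo > hi) {
    warning("trim bounds leave no positions; using untrimmed mean")
    return(mean(s))
  }
  mean(s[lo:hi])
}

#' Normalize viral contig depths and aggregate to family abundance
#'
#' The trimmed-mean depth of each viral contig is divided by the total
#' sequenced length of its sample; family abundance is the per-sample sum
#' over member contigs.  Contigs without a taxonomy assignment aggregate to
#' "unclassified" with a warning.
#'
#' @param depth Data frame (contig_id, sample_id, depth).
#' @param total_bases Named numeric vector of per-sample total sequenced
#'   bases (> 0).
#' @param taxonomy Named character vector contig_id -> family (optional).
#' @return Samples x families matrix with `form` attribute "normalized".
#' @export
normalize_viral <- function(depth, total_bases, taxonomy = NULL) {
  if (any(total_bases <= 0)) stop("total_bases must be > 0", call. = FALSE)
  missing_tot <- setdiff(depth$sample_id, names(total_bases))
  if (length(missing_tot)) {
    stop("no total sequenced length for sample ",
         paste(missing_tot, collapse = ", "), call. = FALSE)
  }
  fam <- if (is.null(taxonomy)) rep(NA_character_, nrow(depth)) else
    unname(taxonomy[depth$contig_id])
  if (anyNA(fam)) {
    warning(sum(is.na(fam)),
            " contig(s) without taxonomy assigned to 'unclassified'")
    fam[is.na(fam)] <- "unclassified"
  }
  value <- depth$depth / total_bases[depth$sample_id]
  samples <- sort(unique(depth$sample_id))
  fams <- sort(unique(fam))
  m <- matrix(0, length(samples), length(fams),
              dimnames = list(samples, fams))
  for (i in seq_along(value)) {
    m[depth$sample_id[i], fam[i]] <- m[depth$sample_id[i], fam[i]] + value[i]
  }
  attr(m, "form") <- "normalized"
  m
}

#' Bacterial relative abundance at taxonomic levels L2..L7
#'
#' Per-genome read counts are divided by genome length; densities are summed
#' into clades at each level and divided by the per-sample per-level total
#' to give relative abundances.
#'
#' @param counts Data frame (genome_id, sample_id, count).
#' @param genome_lengths Named numeric vector (> 0).
#' @param lineage Data frame with column genome_id plus one column per level
#'   (e.g. L2..L7) holding clade names.
#' @return Named list of samples x clades relative matrices, one per level
#'   (`form` attribute "relative").  A sample with zero total gets an
#'   all-zero row with a warning.
#' @export
bacterial_abundance <- function(counts, genome_lengths, lineage) {
  if (any(genome_lengths <= 0)) {
    stop("genome lengths must be > 0", call. = FALSE)
  }
  levels <- setdiff(names(lineage), "genome_id")
  density <- counts$count / genome_lengths[counts$genome_id]
  samples <- sort(unique(counts$sample_id))
  li <- match(counts$genome_id, lineage$genome_id)
  if (anyNA(li)) stop("genome missing from lineage table", call. = FALSE)
  out <- list()
  for (lev in levels) {
    clade <- lineage[[lev]][li]
    clades <- sort(unique(clade))
    m <- matrix(0, length(samples), length(clades),
                dimnames = list(samples, clades))
    for (i in seq_along(density)) {
      m[counts$sample_id[i], clade[i]] <-
        m[counts$sample_id[i], clade[i]] + density[i]
    }
    tot <- rowSums(m)
    zero <- tot == 0
    if (any(zero)) {
      warning("sample(s) with zero total at level ", lev, ": ",
              paste(samples[zero], collapse = ", "))
      tot[zero] <- 1
    }
    m <- m / tot
    attr(m, "form") <- "relative"
    out[[lev]] <- m
  }
  out
}

#' Clade quality control
#'
#' Viral mode retains clades detected (value > 0) in at least one sample of
#' every sequencing batch and in >= 10% of all samples.  Bacterial mode
#' additionally requires >= 20% prevalence and a mean relative abundance
#' strictly above 1e-5 (0.001%).
#'
#' @param m Samples x clades abundance matrix.
#' @param batch Batch label per sample (aligned with rows of `m`).
#' @param mode "viral" or "bacterial".
#' @return Character vector of retained clade names.
#' @export
clade_qc <- function(m, batch, mode = c("viral", "bacterial")) {
  mode <- match.arg(mode)
  if (length(batch) != nrow(m)) {
    stop("batch labels must align with matrix rows", call. = FALSE)
  }
  present <- m > 0
  prevalence <- colMeans(present)
  batches <- unique(batch)
  in_every_batch <- vapply(seq_len(ncol(m)), function(j) {
    all(vapply(batches, function(b) any(present[batch == b, j]),
               logical(1)))
  }, logical(1))
  keep <- if (mode == "viral") {
    in_every_batch & prevalence >= 0.10
  } else {
    in_every_batch & prevalence >= 0.20 & colMeans(m) > 1e-5
  }
  colnames(m)[keep]
}

#' PCA-based outlier sample detection
#'
#' Clades are centred and scaled (constant clades dropped), principal
#' components computed, and a sample flagged when the absolute score on any
#' of the first `n_components` axes exceeds `sd_threshold` times that
#' component's score SD.
#'
#' @param m Samples x clades matrix (>= 3 samples).
#' @param n_components Number of leading components inspected (default 2).
#' @param sd_threshold Score threshold in component SDs (default 4).
#' @return Character vector of outlier sample ids (possibly empty).
#' @export
pca_outliers <- function(m, n_components = 2L, sd_threshold = 4) {
  if (nrow(m) < 3L) stop("need at least 3 samples", call. = FALSE)
  keep <- apply(m, 2, function(x) stats::sd(x) > 0)
  if (!any(keep)) return(character(0))
  p <- stats::prcomp(m[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  k <- min(n_components, ncol(p$x))
  flagged <- rep(FALSE, nrow(m))
  for (j in seq_len(k)) {
    sdj <- stats::sd(p$x[, j])
    if (sdj == 0) next
    flagged <- flagged | abs(p$x[, j]) > sd_threshold * sdj
  }
  rownames(m)[flagged]
}

#' Log10 transform with per-clade pseudocount
#'
#' Default pseudocount is half the smallest positive value of each clade
#' (scale-free compositional convention); a clade with no positive value
#' falls back to half the smallest positive value of the whole matrix, with
#' a warning.
#'
#' @param m Samples x clades nonnegative matrix.
#' @param pseudocount Scalar pseudocount overriding the default.
#' @return Log10-transformed matrix (`form` attribute "log").
#' @export
log_transform <- function(m, pseudocount = NULL) {
  if (any(m < 0)) stop("abundances must be >= 0", call. = FALSE)
  out <- m
  if (!is.null(pseudocount)) {
    out <- log10(m + pseudocount)
  } else {
    global_min <- suppressWarnings(min(m[m > 0]))
    if (!is.finite(global_min)) {
      warning("matrix has no positive entries; using pseudocount 1e-12")
      global_min <- 2e-12
    }
    for (j in seq_len(ncol(m))) {
      pos <- m[, j] > 0
      pc <- if (any(pos)) min(m[pos, j]) / 2 else {
        warning("clade ", colnames(m)[j],
                " has no positive values; using global pseudocount")
        global_min / 2
      }
      out[, j] <- log10(m[, j] + pc)
    }
  }
  attr(out, "form") <- "log"
  out
}

#' Presence/absence transform
#'
#' @param m Samples x clades nonnegative matrix.
#' @return Binary matrix: 1 where value > 0 (`form` attribute "presence").
#' @export
presence_absence <- function(m) {
  out <- (m > 0) * 1
  dimnames(out) <- dimnames(m)
  attr(out, "form") <- "presence"
  out
}
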