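#' Generate synthetic viral and bacterial contigs with ground truth
#'
#' Viral contigs are uniform-composition nucleotide sequences; a configured
#' fraction is made circular by appending an exact terminal repeat (emulating
#' assembly products whose 5' and 3' ends overlap).  Bacterial contigs are
#' all >= 5 kbp so they pass the linear length gate of downstream CRISPR
#' screening.  Each contig is attributed to a synthetic sample; the ground
#' truth records the true viral id set and a true family-level taxonomy drawn
#' over the study's eight QC-passed viral families.
#'
#' @param config A [sim_config()].
#' @param viral_length_range,bacterial_length_range Length bounds (bp) for
#'   the linear portion of generated contigs.
#' @param n_samples Number of synthetic samples contigs are spread over.
#' @return A list with elements `viral` and `bacterial` (contig tables:
#'   id, sequence, length, circular, sample_id) and `truth` (list with
#'   `true_viral_ids`, `true_taxonomy`, `planted_interactions`,
#'   `planted_effects`, `coabundance_pairs`).
#' @export
generate_contigs <- function(config,
                             viral_length_range = c(1500L, 12000L),
                             bacterial_length_range = c(5000L, 15000L),
                             n_samples = 5L) {
  stopifnot(inherits(config, "sim_config"))
  if (any(viral_length_range <= 0) || any(bacterial_length_range <= 0)) {
    stop("contig lengths must be positive", call. = FALSE)
  }
  if (bacterial_length_range[1] < 5000L) {
    stop("bacterial contigs must be >= 5 kbp", call. = FALSE)
  }
  with_component_seed(config$seed, "contigs", {
    nv <- config$n_viral_contigs
    nb <- config$n_bacterial_contigs
    samples <- sprintf("S%03d", seq_len(n_samples))
    fams <- viral_family_names()

    n_circ <- round(config$circular_fraction * nv)
    circular <- rep(c(TRUE, FALSE), c(n_circ, nv - n_circ))
    vlen <- integer(nv)
    vseq <- character(nv)
    for (i in seq_len(nv)) {
      # circular contigs may be short (>=1.5 kbp); linear ones must clear
      # the 5 kbp gate to survive identification
      lo <- if (circular[i]) max(viral_length_range[1], 1500L) else
        max(viral_length_range[1], 5000L)
      hi <- max(viral_length_range[2], lo + 1L)
      len <- sample(lo:hi, 1L)
      s <- random_dna(len)
      if (circular[i]) {
        s <- paste0(s, substr(s, 1L, config$terminal_overlap))
      } else {
        # reject accidental terminal self-overlap so linear stays linear
        while (terminal_overlap_length(s, min_overlap = 50L) >= 50L) {
          s <- random_dna(len)
        }
      }
      vseq[i] <- s
      vlen[i] <- nchar(s)
    }
    viral <- data.frame(
      id = sprintf("vcontig_%03d", seq_len(nv)),
      sequence = vseq,
      length = vlen,
      circular = circular,
      sample_id = rep_len(samples, nv),
      stringsAsFactors = FALSE)

    bseq <- character(nb)
    blen <- integer(nb)
    for (i in seq_len(nb)) {
      len <- sample(bacterial_length_range[1]:bacterial_length_range[2], 1L)
      s <- random_dna(len)
      while (terminal_overlap_length(s, min_overlap = 50L) >= 50L) {
        s <- random_dna(len)
      }
      bseq[i] <- s
      blen[i] <- len
    }
    bacterial <- data.frame(
      id = sprintf("bcontig_%03d", seq_len(nb)),
      sequence = bseq,
      length = blen,
      circular = FALSE,
      sample_id = rep_len(samples, nb),
      stringsAsFactors = FALSE)

    truth <- list(
      true_viral_ids = viral$id,
      true_taxonomy = stats::setNames(
        sample(fams, nv, replace = TRUE), viral$id),
      planted_interactions = data.frame(
        bacterial_contig = character(0), viral_contig = character(0),
        sample_id = character(0), stringsAsFactors = FALSE),
      planted_effects = config$planted_effects,
      coabundance_pairs = config$coabundance_pairs)

    list(viral = viral, bacterial = bacterial, truth = truth)
  })
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Longest exact prefix-suffix overlap, scanning down from the longest
# plausible overlap; used both by the generator's rejection step and by
# circularity detection.
terminal_overlap_length <- function(sequence, min_overlap = 50L) {
  n <- nchar(sequence)
  max_ov <- n %/% 2L
  if (max_ov < min_overlap) return(0L)
  for (k in max_ov:min_overlap) {
    if (substr(sequence, 1L, k) == substr(sequence, n - k + 1L, n)) {
      return(k)
    }
  }
  0L
}

#' Plant CRISPR repeat-spacer arrays into bacterial contigs
#'
#' Inserts arrays of the form repeat-spacer-repeat-...-repeat into randomly
#' chosen bacterial contigs.  Every spacer is an exact copy of a substring of
#' a viral contig from the *same* synthetic sample, so the downstream
#' spacer-matching stage has a recoverable planted signal with known pairs.
#'
#' @param bacterial,viral Contig tables as produced by [generate_contigs()].
#' @param n_arrays Number of arrays to plant.
#' @param repeats_per_array Repeat copies per array (>= 2; k repeats imply
#'   k - 1 spacers).
#' @param seed Seed for the planting stream.
#' @param repeat_len_range,spacer_len_range Sampling windows; kept strictly
#'   inside the detector's published windows (repeats 23-47, spacers 26-50)
#'   so boundary effects of repeat-extension cannot push a planted array out
#'   of bounds.
#' @return List with `bacterial` (modified contig table) and `pairs`
#'   (data frame bacterial_contig, viral_contig, sample_id, one row per
#'   planted array).
#' @export
plant_crispr_arrays <- function(bacterial, viral, n_arrays = 5L,
                                repeats_per_array = 3L, seed = 1L,
                                repeat_len_range = c(25L, 40L),
                                spacer_len_range = c(30L, 45L)) {
  if (repeats_per_array < 2L) {
    stop("repeats_per_array must be >= 2 (detector minimum)", call. = FALSE)
  }
  if (n_arrays == 0L) {
    return(list(bacterial = bacterial,
                pairs = data.frame(bacterial_contig = character(0),
                                   viral_contig = character(0),
                                   sample_id = character(0),
                                   stringsAsFactors = FALSE)))
  }
  if (any(viral$length < max(spacer_len_range))) {
    stop("viral contigs shorter than the maximum spacer length", call. = FALSE)
  }
  with_component_seed(seed, "crispr_plant", {
    pairs <- vector("list", n_arrays)
    for (a in seq_len(n_arrays)) {
      bi <- sample(nrow(bacterial), 1L)
      samp <- bacterial$sample_id[bi]
      vcand <- which(viral$sample_id == samp)
      if (!length(vcand)) {
        stop("no viral contig shares a sample with bacterial contig ",
             bacterial$id[bi], call. = FALSE)
      }
      vi <- if (length(vcand) == 1L) vcand else sample(vcand, 1L)
      rep_len <- sample(repeat_len_range[1]:repeat_len_range[2], 1L)
      repeat_seq <- random_dna(rep_len)
      n_spacers <- repeats_per_array - 1L
      spacers <- character(n_spacers)
      for (s in seq_len(n_spacers)) {
        sp_len <- sample(spacer_len_range[1]:spacer_len_range[2], 1L)
        start <- sample(viral$length[vi] - sp_len + 1L, 1L)
        spacers[s] <- substr(viral$sequence[vi], start, start + sp_len - 1L)
      }
      array_seq <- paste0(repeat_seq,
                          paste0(spacers, repeat_seq, collapse = ""))
      bseq <- bacterial$sequence[bi]
      pos <- sample(nchar(bseq) - 1L, 1L)
      bacterial$sequence[bi] <- paste0(substr(bseq, 1L, pos), array_seq,
                                       substr(bseq, pos + 1L, nchar(bseq)))
      bacterial$length[bi] <- nchar(bacterial$sequence[bi])
      pairs[[a]] <- data.frame(bacterial_contig = bacterial$id[bi],
                               viral_contig = viral$id[vi],
                               sample_id = samp,
                               stringsAsFactors = FALSE)
    }
    list(bacterial = bacterial, pairs = do.call(rbind, pairs))
  })
}

#' Generate classifier evidence for contigs
#'
#' Emits the four external virality/contamination signals the identification
#' stage consumes.  Presets: `"perfect"` gives every true viral contig
#' category 1 with no bacterial-ortholog hits and every bacterial contig
#' category none/score 0, so identification recovers ground truth exactly;
#' `"noisy"` draws scores from overlapping distributions; `"adversarial"`
#' additionally pushes one true viral contig's ortholog/family-hit ratio just
#' above the 0.05 contamination cutoff.
#'
#' @param contigs Combined contig table (viral + bacterial rows).
#' @param truth Ground-truth list from [generate_contigs()].
#' @param config A [sim_config()] (seed source).
#' @param preset One of "perfect", "noisy", "adversarial".
#' @return Evidence table: contig_id, sorter_category, virality_score,
#'   bacterial_ortholog_hits, viral_family_hits.
#' @export
generate_evidence <- function(contigs, truth, config, preset = "perfect") {
  preset <- match.arg(preset, c("perfect", "noisy", "adversarial"))
  if (!all(contigs$id %in% c(truth$true_viral_ids,
                             setdiff(contigs$id, truth$true_viral_ids)))) {
    stop("every contig needs a ground-truth label", call. = FALSE)
  }
  is_viral <- contigs$id %in% truth$true_viral_ids
  n <- nrow(contigs)
  with_component_seed(config$seed, paste0("evidence_", preset), {
    if (preset == "perfect") {
      ev <- data.frame(
        contig_id = contigs$id,
        sorter_category = ifelse(is_viral, "1", "none"),
        virality_score = ifelse(is_viral, 1, 0),
        bacterial_ortholog_hits = 0L,
        viral_family_hits = ifelse(is_viral, 40L, 0L),
        stringsAsFactors = FALSE)
    } else {
      cat_probs_viral <- c("1" = 0.4, "2" = 0.3, "3" = 0.2, "none" = 0.1)
      cat_probs_bact <- c("1" = 0.0, "2" = 0.0, "3" = 0.1, "none" = 0.9)
      ev <- data.frame(
        contig_id = contigs$id,
        sorter_category = ifelse(
          is_viral,
          sample(names(cat_probs_viral), n, TRUE, cat_probs_viral),
          sample(names(cat_probs_bact), n, TRUE, cat_probs_bact)),
        virality_score = ifelse(is_viral,
                                stats::rbeta(n, 8, 1.5),
                                stats::rbeta(n, 1.5, 8)),
        bacterial_ortholog_hits = ifelse(is_viral,
                                         stats::rbinom(n, 1, 0.2),
                                         stats::rpois(n, 8)),
        viral_family_hits = ifelse(is_viral,
                                   30L + stats::rpois(n, 20),
                                   stats::rpois(n, 2)),
        stringsAsFactors = FALSE)
      if (preset == "adversarial" && any(is_viral)) {
        i <- which(is_viral)[1]
        ev$bacterial_ortholog_hits[i] <- 6L
        ev$viral_family_hits[i] <- 100L  # ratio 0.06 > 0.05 -> rejected
      }
    }
    ev
  })
}

#' Generate perfect taxonomy evidence for the nucleotide tier
#'
#' For every true viral contig, emits one nucleotide alignment hit to a
#' synthetic reference accession whose mapped family equals the contig's true
#' family, at full coverage and near-perfect identity.  Contigs whose true
#' family is crAss-like phage hit the reference crAssphage accession
#' NC_024711.1, exercising the family-renaming special case.
#'
#' @param viral Viral contig table.
#' @param truth Ground-truth list.
#' @return List with `nt_hits` (12-column alignment table) and `taxmap`
#'   (accession, family, species).
#' @export
generate_taxonomy_evidence <- function(viral, truth) {
  fams <- sort(unique(unname(truth$true_taxonomy)))
  acc <- ifelse(fams == "crAss-like phage", "NC_024711.1",
                paste0("REF_", gsub("[^A-Za-z]", "", fams)))
  taxmap <- data.frame(accession = acc, family = fams,
                       species = paste0(fams, " virus 1"),
                       stringsAsFactors = FALSE)
  fam_of <- truth$true_taxonomy[viral$id]
  subj <- taxmap$accession[match(fam_of, taxmap$family)]
  nt_hits <- data.frame(
    qseqid = viral$id, sseqid = subj,
    pident = 99.5, length = viral$length,
    mismatch = 0L, gapopen = 0L,
    qstart = 1L, qend = viral$length,
    sstart = 1L, send = viral$length,
    evalue = 1e-180, bitscore = 2 * viral$length,
    stringsAsFactors = FALSE)
  list(nt_hits = nt_hits, taxmap = taxmap)
}

#' Generate per-contig depth tables and per-sample totals
#'
#' Plumbing fixture for the quantification stage: each viral contig gets a
#' log-normal average depth in its own sample; totals mirror the batch-wise
#' sequencing yields of the study design.
#'
#' @param viral Viral contig table.
#' @param config A [sim_config()].
#' @return List with `depth` (contig_id, sample_id, depth) and
#'   `total_bases` (named numeric per sample).
#' @export
generate_depths <- function(viral, config) {
  with_component_seed(config$seed, "depths", {
    samples <- sort(unique(viral$sample_id))
    depth <- data.frame(
      contig_id = viral$id,
      sample_id = viral$sample_id,
      depth = stats::rlnorm(nrow(viral), log(10), 1),
      stringsAsFactors = FALSE)
    total <- stats::setNames(
      stats::rlnorm(length(samples), log(7e9), 0.15), samples)
    list(depth = depth, total_bases = total)
  })
}
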