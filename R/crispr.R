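#' Detect CRISPR repeat-spacer arrays in a contig
#'
#' Seed-and-extend repeat finder in the CRT family: exact 8-mer recurrences
#' whose successive spacings are compatible with a repeat-spacer period seed
#' candidate arrays; each candidate is extended left and right while the
#' per-column agreement across repeat copies stays at or above
#' `1 - max_mismatch_frac`.  An array is accepted when the repeat length,
#' every inter-repeat gap (spacer) and the repeat count satisfy the bounds;
#' chains are split at out-of-bounds gaps.  Overlapping candidates resolve
#' to the one with more repeats, then the longer span.
#'
#' Contigs below 5 kbp are skipped (returned empty), matching the upstream
#' restriction to non-viral contigs of >= 5 kbp.
#'
#' @param sequence Contig nucleotide string.
#' @param min_repeats Minimum repeat copies (default 2, the detector's
#'   `-minNR 2`).
#' @param repeat_len Length window for repeats (default 23-47 bp).
#' @param spacer_len Length window for spacers (default 26-50 bp).
#' @param max_mismatch_frac Maximum per-column disagreement during repeat
#'   extension (default 0.1).
#' @param k Seed k-mer size (default 8).
#' @param min_length Minimum contig length to scan (default 5000).
#' @return List of arrays; each has `repeat_consensus`, `repeat_count`,
#'   `repeat_starts`, `spacers` (data frame sequence/start/end, 1-based
#'   inclusive) and `span` (c(start, end)).
#' @export
detect_crispr_arrays <- function(sequence, min_repeats = 2L,
                                 repeat_len = c(23L, 47L),
                                 spacer_len = c(26L, 50L),
                                 max_mismatch_frac = 0.1,
                                 k = 8L, min_length = 5000L) {
  n <- nchar(sequence)
  if (n < min_length) return(list())
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  period_min <- repeat_len[1] + spacer_len[1]
  period_max <- repeat_len[2] + spacer_len[2]

  kmers <- substring(sequence, 1:(n - k + 1L), k:n)
  occ <- split(seq_len(n - k + 1L), kmers)
  occ <- occ[lengths(occ) >= min_repeats]

  candidates <- list()
  seen <- character(0)
  for (pos in occ) {
    pos <- sort(pos)
    gaps <- diff(pos)
    chain_ok <- gaps >= period_min & gaps <= period_max
    # maximal runs of compatible spacings
    runs <- split(seq_along(pos),
                  cumsum(c(TRUE, !chain_ok)))
    for (idx in runs) {
      if (length(idx) < min_repeats) next
      anchors <- pos[idx]
      arr <- extend_repeat(chars, anchors, k, repeat_len, spacer_len,
                           max_mismatch_frac, min_repeats, n)
      for (a in arr) {
        key <- paste(a$repeat_starts, collapse = ",")
        if (key %in% seen) next
        seen <- c(seen, key)
        candidates[[length(candidates) + 1L]] <- a
      }
    }
  }
  if (!length(candidates)) return(list())
  resolve_overlaps(candidates)
}

# Extend aligned anchor positions into full repeats; returns zero or more
# validated arrays (chains are split at gaps outside the spacer window).
extend_repeat <- function(chars, anchors, k, repeat_len, spacer_len,
                          max_mismatch_frac, min_repeats, n) {
  m <- length(anchors)
  agree <- function(offsets) {
    b <- chars[offsets]
    tab <- table(b)
    max(tab) / m
  }
  # extend left
  left <- 0L
  repeat {
    offs <- anchors - left - 1L
    if (any(offs < 1L)) break
    if (k + left + 1L > repeat_len[2]) break
    if (agree(offs) < 1 - max_mismatch_frac) break
    left <- left + 1L
  }
  right <- 0L
  repeat {
    offs <- anchors + k + right
    if (any(offs > n)) break
    if (k + left + right + 1L > repeat_len[2]) break
    if (agree(offs) < 1 - max_mismatch_frac) break
    right <- right + 1L
  }
  rep_len <- k + left + right
  starts <- anchors - left
  # guard against extension running into the next repeat copy
  gaps <- diff(starts) - rep_len
  if (rep_len < repeat_len[1] || rep_len > repeat_len[2]) return(list())

  gap_ok <- gaps >= spacer_len[1] & gaps <= spacer_len[2]
  runs <- split(seq_along(starts), cumsum(c(TRUE, !gap_ok)))
  out <- list()
  for (idx in runs) {
    if (length(idx) < min_repeats) next
    st <- starts[idx]
    consensus <- consensus_repeat(chars, st, rep_len)
    sp_start <- st[-length(st)] + rep_len
    sp_end <- st[-1] - 1L
    spacers <- data.frame(
      sequence = vapply(seq_along(sp_start), function(j) {
        paste(chars[sp_start[j]:sp_end[j]], collapse = "")
      }, character(1)),
      start = sp_start, end = sp_end, stringsAsFactors = FALSE)
    out[[length(out) + 1L]] <- list(
      repeat_consensus = consensus,
      repeat_count = length(st),
      repeat_starts = st,
      spacers = spacers,
      span = c(st[1], st[length(st)] + rep_len - 1L))
  }
  out
}

consensus_repeat <- function(chars, starts, rep_len) {
  cols <- vapply(seq_len(rep_len) - 1L, function(off) {
    b <- chars[starts + off]
    tab <- sort(table(b), decreasing = TRUE)
    names(tab)[1]
  }, character(1))
  paste(cols, collapse = "")
}

resolve_overlaps <- function(candidates) {
  spans <- t(vapply(candidates, function(a) a$span, numeric(2)))
  counts <- vapply(candidates, function(a) a$repeat_count, numeric(1))
  widths <- spans[, 2] - spans[, 1]
  ord <- order(-counts, -widths, spans[, 1])
  kept <- list()
  kept_spans <- matrix(numeric(0), ncol = 2)
  for (i in ord) {
    s <- spans[i, ]
    if (nrow(kept_spans)) {
      overlap <- kept_spans[, 1] <= s[2] & kept_spans[, 2] >= s[1]
      if (any(overlap)) next
    }
    kept[[length(kept) + 1L]] <- candidates[[i]]
    kept_spans <- rbind(kept_spans, s)
  }
  kept[order(vapply(kept, function(a) a$span[1], numeric(1)))]
}

#' Assign a bacterial host taxon to a CRISPR-carrying contig
#'
#' Filters the contig's nucleotide hits against reference bacterial genomes
#' (E-value < 1e-10, identity > 95, query coverage >= 0.90) and returns the
#' taxon of the highest-bit-score survivor; bit-score ties break toward the
#' lexicographically smaller genome id.
#'
#' @param contig_id,contig_length Query contig.
#' @param hits 12-column alignment table (query = contig).
#' @param genome_taxonomy Named character vector genome id -> taxon label
#'   (species or genus, as provided).
#' @param max_evalue,min_identity,min_coverage Filter thresholds.
#' @return Taxon string or NA when no hit survives.
#' @export
assign_host <- function(contig_id, contig_length, hits, genome_taxonomy,
                        max_evalue = 1e-10, min_identity = 95,
                        min_coverage = 0.90) {
  h <- hits[hits$qseqid == contig_id, , drop = FALSE]
  if (!nrow(h)) return(NA_character_)
  keep <- h$evalue < max_evalue & h$pident > min_identity &
    (h$length / contig_length) >= min_coverage
  h <- h[keep, , drop = FALSE]
  if (!nrow(h)) return(NA_character_)
  h <- h[order(-h$bitscore, h$sseqid), , drop = FALSE]
  best <- h$sseqid[1]
  if (!best %in% names(genome_taxonomy)) {
    stop("taxonomy missing for genome ", best, call. = FALSE)
  }
  unname(genome_taxonomy[best])
}

#' Match CRISPR spacers against same-sample viral contigs
#'
#' Both strands are searched.  A candidate placement passes when its matched
#' length is at least 90% of the spacer length and the identity over the
#' matched span exceeds 95% (for a 30-bp spacer: at most one mismatch over a
#' >= 27 bp match).  Among passing placements the score
#' `matched_length - 2 x mismatches` decides, ties broken by smaller contig
#' id then smaller start coordinate.  Only viral contigs supplied by the
#' caller are searched, which enforces the within-sample restriction.
#'
#' @param spacers Character vector of spacer sequences (20-60 bp).
#' @param viral Contig table (id, sequence) of the spacer's sample.
#' @param min_coverage Matched-length fraction (default 0.90).
#' @param min_identity Identity over the matched span, strict (default 95).
#' @return Data frame, one row per spacer: spacer, contig_id (NA when
#'   unmatched), start, end, strand, score, mismatches.
#' @export
match_spacers <- function(spacers, viral, min_coverage = 0.90,
                          min_identity = 95) {
  if (length(spacers) && any(nchar(spacers) < 20L | nchar(spacers) > 60L)) {
    stop("spacers must be 20-60 bp", call. = FALSE)
  }
  out <- vector("list", length(spacers))
  viral <- viral[order(viral$id), , drop = FALSE]
  for (si in seq_along(spacers)) {
    sp <- spacers[si]
    L <- nchar(sp)
    min_len <- as.integer(ceiling(min_coverage * L))
    best <- NULL
    for (ci in seq_len(nrow(viral))) {
      for (strand in c("+", "-")) {
        subject <- if (strand == "+") viral$sequence[ci] else
          revcomp(viral$sequence[ci])
        cand <- spacer_placements(sp, subject, min_len, min_identity)
        if (is.null(cand)) next
        slen <- nchar(subject)
        for (r in seq_len(nrow(cand))) {
          start <- if (strand == "+") cand$start[r] else
            slen - cand$end[r] + 1L
          end <- if (strand == "+") cand$end[r] else
            slen - cand$start[r] + 1L
          rec <- list(contig_id = viral$id[ci], start = start, end = end,
                      strand = strand, score = cand$score[r],
                      mismatches = cand$mismatches[r])
          if (is.null(best) || rec$score > best$score ||
              (rec$score == best$score &&
               (rec$contig_id < best$contig_id ||
                (rec$contig_id == best$contig_id &&
                 rec$start < best$start)))) {
            best <- rec
          }
        }
      }
    }
    out[[si]] <- if (is.null(best)) {
      data.frame(spacer = sp, contig_id = NA_character_, start = NA_integer_,
                 end = NA_integer_, strand = NA_character_, score = NA_real_,
                 mismatches = NA_integer_, stringsAsFactors = FALSE)
    } else {
      data.frame(spacer = sp, contig_id = best$contig_id,
                 start = best$start, end = best$end, strand = best$strand,
                 score = best$score, mismatches = best$mismatches,
                 stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# All passing (possibly end-trimmed) placements of a spacer on one strand of
# a subject.  Fast path: full-length placements with a small mismatch budget
# found via matchPattern; each is then optimally trimmed.
spacer_placements <- function(spacer, subject, min_len, min_identity) {
  L <- nchar(spacer)
  budget <- (L - min_len) + floor(L * (1 - min_identity / 100))
  mp <- Biostrings::matchPattern(spacer, Biostrings::DNAString(subject),
                                 max.mismatch = budget,
                                 with.indels = FALSE)
  if (!length(mp)) return(NULL)
  sp_chars <- strsplit(spacer, "", fixed = TRUE)[[1]]
  res <- list()
  for (i in seq_along(mp)) {
    s0 <- Biostrings::start(mp)[i]
    seg <- substr(subject, s0, s0 + L - 1L)
    if (nchar(seg) < L) next
    mism <- strsplit(seg, "", fixed = TRUE)[[1]] != sp_chars
    tr <- best_trimmed_window(mism, min_len, min_identity)
    if (is.null(tr)) next
    res[[length(res) + 1L]] <- data.frame(
      start = s0 + tr$from - 1L, end = s0 + tr$to - 1L,
      score = tr$score, mismatches = tr$mismatches)
  }
  if (!length(res)) return(NULL)
  do.call(rbind, res)
}

# Optimal end-trimming of a full-length placement: over all windows of
# length >= min_len, maximize matched_length - 2*mismatches subject to
# identity > min_identity; trimming interior bases never helps, so the
# O(L^2) window scan is exact.
best_trimmed_window <- function(mism, min_len, min_identity) {
  L <- length(mism)
  cs <- c(0L, cumsum(mism))
  best <- NULL
  for (from in seq_len(L - min_len + 1L)) {
    for (to in seq(from + min_len - 1L, L)) {
      m <- cs[to + 1L] - cs[from]
      len <- to - from + 1L
      if ((len - m) / len * 100 <= min_identity) next
      score <- len - 2L * m
      if (is.null(best) || score > best$score) {
        best <- list(from = from, to = to, score = score, mismatches = m)
      }
    }
  }
  best
}

#' Summarize virus-host interaction pairs across samples
#'
#' Within each sample, duplicate (virus taxon, host taxon) pairs collapse to
#' one; across samples, each unique pair is reported with the number of
#' contributing samples and the total supporting spacers.
#'
#' @param pairs Data frame (sample_id, virus_taxon, host_taxon), one row per
#'   taxonomically annotated spacer match.
#' @return Data frame (virus_taxon, host_taxon, supporting_samples,
#'   supporting_spacers), sorted.
#' @export
summarize_interactions <- function(pairs) {
  if (is.null(pairs) || !nrow(pairs)) {
    return(data.frame(virus_taxon = character(0),
                      host_taxon = character(0),
                      supporting_samples = integer(0),
                      supporting_spacers = integer(0),
                      stringsAsFactors = FALSE))
  }
  key <- paste(pairs$virus_taxon, pairs$host_taxon, sep = "\r")
  spacer_count <- table(key)
  per_sample <- unique(pairs[, c("sample_id", "virus_taxon", "host_taxon")])
  skey <- paste(per_sample$virus_taxon, per_sample$host_taxon, sep = "\r")
  sample_count <- table(skey)
  uk <- sort(unique(key))
  parts <- strsplit(uk, "\r", fixed = TRUE)
  data.frame(
    virus_taxon = vapply(parts, `[`, character(1), 1L),
    host_taxon = vapply(parts, `[`, character(1), 2L),
    supporting_samples = as.integer(sample_count[uk]),
    supporting_spacers = as.integer(spacer_count[uk]),
    stringsAsFactors = FALSE)
}

#' End-to-end CRISPR virus-host interaction calling
#'
#' Scans non-viral contigs for repeat-spacer arrays, assigns each
#' CRISPR-carrying contig a bacterial host taxon (from alignment hits when
#' provided, else the contig's own id), matches spacers against viral
#' contigs of the same sample, annotates matches with viral taxonomy, and
#' summarizes unique interactions across samples.
#'
#' @param nonviral Contig table (id, sequence, sample_id).
#' @param viral Contig table (id, sequence, sample_id).
#' @param host_hits Optional alignment table of non-viral contigs vs
#'   reference genomes.
#' @param genome_taxonomy Named vector genome id -> taxon (required with
#'   `host_hits`).
#' @param viral_taxonomy Optional named vector viral contig id -> taxon;
#'   defaults to the contig id itself.
#' @param ... Passed to [detect_crispr_arrays()].
#' @return List with `arrays` (per-contig array tables), `matches`
#'   (spacer-match rows) and `interactions` (summary table).
#' @export
find_crispr_interactions <- function(nonviral, viral, host_hits = NULL,
                                     genome_taxonomy = NULL,
                                     viral_taxonomy = NULL, ...) {
  if (is.null(viral_taxonomy)) {
    viral_taxonomy <- stats::setNames(viral$id, viral$id)
  }
  all_pairs <- list()
  all_matches <- list()
  arrays_out <- list()
  for (ci in seq_len(nrow(nonviral))) {
    arrays <- detect_crispr_arrays(nonviral$sequence[ci], ...)
    if (!length(arrays)) next
    arrays_out[[nonviral$id[ci]]] <- arrays
    host <- if (!is.null(host_hits)) {
      assign_host(nonviral$id[ci], nchar(nonviral$sequence[ci]),
                  host_hits, genome_taxonomy)
    } else nonviral$id[ci]
    if (is.na(host)) next
    samp <- nonviral$sample_id[ci]
    vsub <- viral[viral$sample_id == samp, , drop = FALSE]
    if (!nrow(vsub)) next
    spacers <- unlist(lapply(arrays, function(a) a$spacers$sequence))
    mt <- match_spacers(spacers, vsub)
    mt$host_contig <- nonviral$id[ci]
    mt$sample_id <- samp
    all_matches[[length(all_matches) + 1L]] <- mt
    hit <- !is.na(mt$contig_id)
    if (any(hit)) {
      all_pairs[[length(all_pairs) + 1L]] <- data.frame(
        sample_id = samp,
        virus_taxon = unname(viral_taxonomy[mt$contig_id[hit]]),
        host_taxon = host,
        stringsAsFactors = FALSE)
    }
  }
  list(arrays = arrays_out,
       matches = if (length(all_matches)) do.call(rbind, all_matches) else
         NULL,
       interactions = summarize_interactions(
         if (length(all_pairs)) do.call(rbind, all_pairs) else NULL))
}
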