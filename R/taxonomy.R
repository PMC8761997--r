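#' Nucleotide-tier taxonomic assignment
#'
#' Filters nucleotide alignment hits of one contig against reference viral
#' genomes (E-value < 1e-10, identity > 95, query coverage
#' `alignment_length / contig_length >= 0.85`), then assigns the taxonomy of
#' the highest-bit-score surviving hit.  Bit-score ties break toward the
#' lexicographically smallest subject accession for determinism.  A best hit
#' to the reference crAssphage accession `NC_024711.1` is reported at family
#' level as "crAss-like phage".
#'
#' @param contig_id Contig id (hits are pre-filtered to this query).
#' @param contig_length Contig length in bp.
#' @param hits 12-column alignment table.
#' @param taxmap Data frame with columns accession, family, species.
#' @param max_evalue,min_identity,min_coverage Filter thresholds.
#' @return A one-row assignment data frame (contig_id, family, finer_rank,
#'   tier) or NULL when no hit survives.
#' @export
assign_nucleotide_tier <- function(contig_id, contig_length, hits, taxmap,
                                   max_evalue = 1e-10, min_identity = 95,
                                   min_coverage = 0.85) {
  h <- hits[hits$qseqid == contig_id, , drop = FALSE]
  if (!nrow(h)) return(NULL)
  keep <- h$evalue < max_evalue & h$pident > min_identity &
    (h$length / contig_length) >= min_coverage
  h <- h[keep, , drop = FALSE]
  if (!nrow(h)) return(NULL)
  h <- h[order(-h$bitscore, h$sseqid), , drop = FALSE]
  best <- h[1, ]
  mi <- match(best$sseqid, taxmap$accession)
  if (is.na(mi)) {
    stop("subject ", best$sseqid, " missing from taxonomy map",
         call. = FALSE)
  }
  family <- if (best$sseqid == "NC_024711.1") "crAss-like phage" else
    taxmap$family[mi]
  data.frame(contig_id = contig_id, family = family,
             finer_rank = taxmap$species[mi], tier = "nucleotide",
             stringsAsFactors = FALSE)
}

#' Detect the crAss-like phage protein signature
#'
#' True when any protein-level hit between the contig's ORFs and the two
#' crAssphage signature proteins (polymerase UGP_018, terminase UGP_092)
#' has E-value < 1e-5 and alignment length >= 350.
#'
#' @param hits Protein alignment table restricted to signature-vs-ORF
#'   comparisons for one contig (subject ids UGP_018/UGP_092 or arbitrary
#'   when the caller pre-filtered).
#' @param max_evalue,min_length Thresholds.
#' @return Logical scalar.
#' @export
detect_crass_signature <- function(hits, max_evalue = 1e-5,
                                   min_length = 350L) {
  if (is.null(hits) || !nrow(hits)) return(FALSE)
  any(hits$evalue < max_evalue & hits$length >= min_length)
}

#' Family assignment by ORF majority voting
#'
#' Contigs with fewer than two annotated ORFs are unclassified.  Otherwise
#' the family held by a strict majority (> half) of annotated ORFs wins; a
#' tie or absent majority leaves the contig unclassified.  A plurality mode
#' (most frequent family, ties unclassified) is available behind `mode`.
#'
#' @param families Character vector: one best-hit family per annotated ORF
#'   of a single contig.
#' @param mode "strict" (default) or "plurality".
#' @return Family name or "unclassified".
#' @export
vote_family <- function(families, mode = c("strict", "plurality")) {
  mode <- match.arg(mode)
  families <- families[!is.na(families) & nzchar(families)]
  n <- length(families)
  if (n < 2L) return("unclassified")
  tab <- sort(table(families), decreasing = TRUE)
  if (mode == "strict") {
    if (tab[1] * 2L > n) names(tab)[1] else "unclassified"
  } else {
    if (length(tab) > 1L && tab[1] == tab[2]) "unclassified" else
      names(tab)[1]
  }
}

#' Three-tier cascade taxonomic annotation of viral contigs
#'
#' Tier order: nucleotide best hit against reference genomes, then the
#' crAss-like signature-protein test, then ORF-majority voting; the first
#' tier producing an assignment wins and exactly one tier label is recorded
#' per contig.
#'
#' @param contigs Viral contig table (id, sequence or length).
#' @param nt_hits Nucleotide alignment table (all contigs).
#' @param taxmap Reference taxonomy map (accession, family, species).
#' @param crass_hits Optional protein alignment table of signature proteins
#'   vs ORFs; rows are attributed to contigs via `qseqid` of the form
#'   `<contig_id>|<orf>` or an explicit `contig_id` column.
#' @param orf_annotations Optional data frame (contig_id, orf_id, family,
#'   bitscore) of best-hit ORF annotations.
#' @param vote_mode Passed to [vote_family()].
#' @return Assignment table: contig_id, family, finer_rank, tier.
#' @export
cascade_annotate <- function(contigs, nt_hits, taxmap, crass_hits = NULL,
                             orf_annotations = NULL,
                             vote_mode = "strict") {
  lens <- if ("length" %in% names(contigs)) contigs$length else
    nchar(contigs$sequence)
  out <- vector("list", nrow(contigs))
  crass_contig <- crass_hit_contigs(crass_hits)
  for (i in seq_len(nrow(contigs))) {
    id <- contigs$id[i]
    a <- assign_nucleotide_tier(id, lens[i], nt_hits, taxmap)
    if (is.null(a)) {
      ch <- if (!is.null(crass_hits))
        crass_hits[crass_contig == id, , drop = FALSE] else NULL
      if (detect_crass_signature(ch)) {
        a <- data.frame(contig_id = id, family = "crAss-like phage",
                        finer_rank = NA_character_,
                        tier = "crass_signature", stringsAsFactors = FALSE)
      } else {
        fams <- if (!is.null(orf_annotations)) {
          orf_annotations$family[orf_annotations$contig_id == id]
        } else character(0)
        fam <- vote_family(fams, mode = vote_mode)
        a <- data.frame(contig_id = id, family = fam,
                        finer_rank = NA_character_,
                        tier = if (fam == "unclassified") "unclassified"
                               else "orf_vote",
                        stringsAsFactors = FALSE)
      }
    }
    out[[i]] <- a
  }
  do.call(rbind, out)
}

crass_hit_contigs <- function(crass_hits) {
  if (is.null(crass_hits) || !nrow(crass_hits)) return(character(0))
  if ("contig_id" %in% names(crass_hits)) return(crass_hits$contig_id)
  sub("\\|.*$", "", crass_hits$qseqid)
}

#' Naive ORF finder for synthetic fixtures
#'
#' Reports open reading frames (ATG..stop, >= `min_codons` codons) on all
#' six frames.  This is a convenience for building synthetic ORF tables
#' only; real pipelines consume the output of a dedicated gene predictor.
#'
#' @param sequence Nucleotide string.
#' @param min_codons Minimum ORF length in codons (default 60).
#' @return Data frame (start, end, strand, protein) in 1-based forward
#'   coordinates.
#' @export
find_orfs <- function(sequence, min_codons = 60L) {
  res <- list()
  n <- nchar(sequence)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") sequence else revcomp(sequence)
    prot <- suppressWarnings(lapply(0:2, function(off) {
      sub <- substr(s, off + 1L, n - (n - off) %% 3L)
      if (nchar(sub) < 3L) return(NULL)
      aa <- as.character(Biostrings::translate(
        Biostrings::DNAString(sub), if.fuzzy.codon = "X"))
      list(offset = off, aa = aa)
    }))
    for (fr in prot) {
      if (is.null(fr)) next
      aa <- fr$aa
      starts <- gregexpr("M[^*]+\\*", aa)[[1]]
      if (starts[1] == -1L) next
      lens <- attr(starts, "match.length")
      for (j in seq_along(starts)) {
        if (lens[j] - 1L < min_codons) next
        a1 <- starts[j]; a2 <- starts[j] + lens[j] - 1L
        nt1 <- fr$offset + (a1 - 1L) * 3L + 1L
        nt2 <- fr$offset + a2 * 3L
        if (strand == "+") {
          res[[length(res) + 1L]] <- data.frame(
            start = nt1, end = nt2, strand = strand,
            protein = substr(aa, a1, a2 - 1L), stringsAsFactors = FALSE)
        } else {
          res[[length(res) + 1L]] <- data.frame(
            start = n - nt2 + 1L, end = n - nt1 + 1L, strand = strand,
            protein = substr(aa, a1, a2 - 1L), stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(res)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), protein = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, res)
}

revcomp <- function(sequence) {
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(sequence)))
}
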