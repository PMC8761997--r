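#' Detect assembly circularity from terminal overlap
#'
#' A contig is called circular when its 5' and 3' terminals share an exact
#' overlap of at least `min_overlap` bp (the longest exact prefix-suffix
#' match is compared against the threshold).  Contigs shorter than twice the
#' overlap cannot be circular and return `FALSE`.
#'
#' @param sequence Nucleotide string (A/C/G/T/N).
#' @param min_overlap Minimum exact terminal overlap in bp (default 50).
#' @return Logical scalar.
#' @export
detect_circularity <- function(sequence, min_overlap = 50L) {
  if (nchar(sequence) < 2L * min_overlap) return(FALSE)
  terminal_overlap_length(sequence, min_overlap = min_overlap) >= min_overlap
}

#' Length gate for candidate viral contigs
#'
#' Linear contigs must be >= 5 kbp and circular contigs >= 1.5 kbp to enter
#' viral classification (both thresholds inclusive).
#'
#' @param length Contig length in bp.
#' @param circular Logical circularity flag.
#' @param min_linear,min_circular Thresholds in bp.
#' @return Logical vector.
#' @export
length_gate <- function(length, circular, min_linear = 5000L,
                        min_circular = 1500L) {
  ifelse(circular, length >= min_circular, length >= min_linear)
}

#' Classify a contig as viral from sorter category and virality score
#'
#' Decision tree: sorter confidence categories 1 and 2 are accepted
#' outright; category 3 needs a machine-learning virality score >= 0.7;
#' unsorted contigs (category "none") need a score >= 0.9.  The rule label
#' records the first branch that fired (category order 1/2, then 3, then
#' high score).
#'
#' @param category Sorter confidence category: "1", "2", "3" or "none"
#'   (integers accepted).
#' @param score Virality score in `[0, 1]`.
#' @param score_mid Score cutoff for category-3 contigs (default 0.7).
#' @param score_high Score cutoff for unsorted contigs (default 0.9).
#' @return List with `viral` (logical) and `rule` (character label:
#'   "category_1_2", "category_3_score", "high_score" or "none").
#' @export
classify_viral <- function(category, score, score_mid = 0.7,
                           score_high = 0.9) {
  category <- as.character(category)
  if (!category %in% c("1", "2", "3", "none")) {
    stop("unknown sorter category: ", category, call. = FALSE)
  }
  if (is.na(score) || score < 0 || score > 1) {
    stop("virality score must lie in [0, 1]", call. = FALSE)
  }
  if (category %in% c("1", "2")) {
    list(viral = TRUE, rule = "category_1_2")
  } else if (category == "3" && score >= score_mid) {
    list(viral = TRUE, rule = "category_3_score")
  } else if (category == "none" && score >= score_high) {
    list(viral = TRUE, rule = "high_score")
  } else {
    list(viral = FALSE, rule = "none")
  }
}

#' Bacterial-contamination filter
#'
#' Rejects a candidate viral contig when its ratio of bacterial single-copy
#' ortholog hits to viral-protein-family hits exceeds 0.05 (strict: a ratio
#' of exactly 0.05 is kept).  Conventions for a zero denominator: ortholog
#' hits with no family hits reject (infinite ratio); zero over zero keeps
#' (no evidence either way).
#'
#' @param ortholog_hits Bacterial single-copy ortholog hit count.
#' @param family_hits Viral protein family hit count.
#' @param max_ratio Rejection threshold (default 0.05, strict `>`).
#' @return TRUE to keep, FALSE to reject.
#' @export
contamination_filter <- function(ortholog_hits, family_hits,
                                 max_ratio = 0.05) {
  if (ortholog_hits < 0 || family_hits < 0) {
    stop("hit counts must be >= 0", call. = FALSE)
  }
  if (family_hits == 0) return(ortholog_hits == 0)
  (ortholog_hits / family_hits) <= max_ratio
}

#' Identify viral contigs from evidence, with an audit trail
#'
#' Applies, in order, circularity detection, the length gate, the
#' category/score decision tree and the contamination filter.  Every gated
#' contig must have an evidence row; a missing row is an error naming the
#' contig.
#'
#' @param contigs Contig table (id, sequence, length, circular, sample_id);
#'   the circular flag is recomputed from the sequence.
#' @param evidence Evidence table (contig_id, sorter_category,
#'   virality_score, bacterial_ortholog_hits, viral_family_hits).
#' @param score_mid,score_high,max_ratio Thresholds, defaulting to the
#'   published values.
#' @return List with `viral_ids` (character) and `audit` (one row per
#'   contig: gate outcomes, rule labels, final decision).
#' @export
identify_viral_contigs <- function(contigs, evidence, score_mid = 0.7,
                                   score_high = 0.9, max_ratio = 0.05) {
  n <- nrow(contigs)
  if (!n) {
    return(list(viral_ids = character(0),
                audit = data.frame(contig_id = character(0),
                                   circular = logical(0),
                                   length_pass = logical(0),
                                   classifier_rule = character(0),
                                   classifier_pass = logical(0),
                                   contamination_pass = logical(0),
                                   viral = logical(0),
                                   stringsAsFactors = FALSE)))
  }
  circ <- vapply(contigs$sequence, detect_circularity, logical(1),
                 USE.NAMES = FALSE)
  lpass <- length_gate(nchar(contigs$sequence), circ)
  rule <- rep("not_gated", n)
  cpass <- rep(NA, n)
  fpass <- rep(NA, n)
  ev_idx <- match(contigs$id, evidence$contig_id)
  for (i in seq_len(n)) {
    if (!lpass[i]) next
    if (is.na(ev_idx[i])) {
      stop("missing evidence row for contig ", contigs$id[i], call. = FALSE)
    }
    e <- evidence[ev_idx[i], ]
    cls <- classify_viral(e$sorter_category, e$virality_score,
                          score_mid = score_mid, score_high = score_high)
    rule[i] <- cls$rule
    cpass[i] <- cls$viral
    fpass[i] <- contamination_filter(e$bacterial_ortholog_hits,
                                     e$viral_family_hits,
                                     max_ratio = max_ratio)
  }
  final <- lpass & !is.na(cpass) & cpass & !is.na(fpass) & fpass
  audit <- data.frame(contig_id = contigs$id,
                      circular = circ,
                      length_pass = lpass,
                      classifier_rule = rule,
                      classifier_pass = cpass,
                      contamination_pass = fpass,
                      viral = final,
                      stringsAsFactors = FALSE)
  list(viral_ids = contigs$id[final], audit = audit)
}
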