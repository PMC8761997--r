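test_that("a planted three-repeat array is detected at its coordinates", {
  pc <- planted_crispr_contig()
  arrays <- detect_crispr_arrays(pc$sequence)
  expect_length(arrays, 1)
  a <- arrays[[1]]
  expect_equal(a$repeat_count, 3)
  expect_identical(a$repeat_consensus, pc$repeat_seq)
  expect_identical(a$spacers$sequence, pc$spacers)
  expect_equal(a$span, c(pc$array_start, pc$array_end))
  # spacer coordinates are 1-based inclusive substrings of the contig
  for (i in seq_len(nrow(a$spacers))) {
    expect_identical(substr(pc$sequence, a$spacers$start[i],
                            a$spacers$end[i]),
                     a$spacers$sequence[i])
  }
})

test_that("arrays out of spec are rejected", {
  set.seed(14)
  rnd <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = "")
  rep_seq <- rnd(30)
  # two copies 500 bp apart: gap exceeds the 50 bp spacer maximum
  far <- paste0(rnd(2500), rep_seq, rnd(500), rep_seq, rnd(2500))
  expect_length(detect_crispr_arrays(far), 0)
  # a single occurrence can never seed an array
  single <- paste0(rnd(3000), rep_seq, rnd(3000))
  expect_length(detect_crispr_arrays(single), 0)
  # contigs below 5 kbp are skipped
  pc <- planted_crispr_contig()
  expect_length(detect_crispr_arrays(substr(pc$sequence, 1500, 6000),
                                     min_length = 5000), 0)
  # random sequence carries no arrays (false-positive control)
  expect_length(detect_crispr_arrays(rnd(20000)), 0)
})

test_that("array detection is strand-symmetric", {
  pc <- planted_crispr_contig(seed = 17)
  n <- nchar(pc$sequence)
  fwd <- detect_crispr_arrays(pc$sequence)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(pc$sequence)))
  rev <- detect_crispr_arrays(rc)
  expect_length(rev, length(fwd))
  expect_equal(sort(n - fwd[[1]]$span + 1L), sort(rev[[1]]$span))
})

test_that("spacer count equals repeats minus one across arrays", {
  for (seed in c(3, 9, 27)) {
    cfg <- small_config(seed = seed)
    ctg <- generate_contigs(cfg)
    pl <- plant_crispr_arrays(ctg$bacterial, ctg$viral, n_arrays = 3,
                              repeats_per_array = 4, seed = seed)
    arrays <- unlist(lapply(pl$bacterial$sequence, detect_crispr_arrays),
                     recursive = FALSE)
    n_spacers <- sum(vapply(arrays, function(a) nrow(a$spacers), numeric(1)))
    n_repeats <- sum(vapply(arrays, function(a) a$repeat_count, numeric(1)))
    expect_equal(n_spacers, n_repeats - length(arrays))
  }
})

test_that("host assignment filters on e-value, identity and 90% coverage", {
  hit <- function(s, len, bits, pident = 99, e = 1e-50) {
    data.frame(qseqid = "b1", sseqid = s, pident = pident, length = len,
               mismatch = 0L, gapopen = 0L, qstart = 1L, qend = len,
               sstart = 1L, send = len, evalue = e, bitscore = bits,
               stringsAsFactors = FALSE)
  }
  taxo <- c(gA = "Faecalibacterium spp", gB = "Ruminococcus spp")
  expect_identical(assign_host("b1", 1000, hit("gA", 950, 800), taxo),
                   "Faecalibacterium spp")
  expect_true(is.na(assign_host("b1", 1000, hit("gA", 890, 800), taxo)))
  expect_true(is.na(assign_host("b1", 1000,
                                hit("gA", 950, 800, pident = 95), taxo)))
  tie <- rbind(hit("gB", 950, 800), hit("gA", 950, 800))
  expect_identical(assign_host("b1", 1000, tie, taxo),
                   "Faecalibacterium spp")  # lexicographic on genome id
  expect_error(assign_host("b1", 1000, hit("gX", 950, 800), taxo),
               "taxonomy missing")
})

test_that("spacer matching honors coverage, identity and strand", {
  set.seed(19)
  contig <- paste(sample(c("A", "C", "G", "T"), 4000, TRUE), collapse = "")
  viral <- data.frame(id = "v1", sequence = contig, sample_id = "S1",
                      stringsAsFactors = FALSE)
  sp <- substr(contig, 1001, 1030)
  m <- match_spacers(sp, viral)
  expect_identical(m$contig_id, "v1")
  expect_equal(c(m$start, m$end), c(1001, 1030))
  expect_identical(m$strand, "+")

  # reverse-complement spacer matches on the minus strand, same span
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sp)))
  mrc <- match_spacers(rc, viral)
  expect_identical(mrc$strand, "-")
  expect_equal(c(mrc$start, mrc$end), c(1001, 1030))

  # two interior mismatches on a 30-mer: identity 93.3% < 95, and no >= 27 bp
  # window avoids both, so the spacer must go unmatched
  bad <- sp
  flip <- function(b) c(A = "C", C = "A", G = "T", T = "G")[b]
  substr(bad, 5, 5) <- flip(substr(sp, 5, 5))
  substr(bad, 25, 25) <- flip(substr(sp, 25, 25))
  expect_true(is.na(match_spacers(bad, viral)$contig_id))

  # one trailing mismatch is rescued by end-trimming
  one <- sp
  substr(one, 30, 30) <- flip(substr(sp, 30, 30))
  m1 <- match_spacers(one, viral)
  expect_identical(m1$contig_id, "v1")
  expect_error(match_spacers("ACGT", viral), "20-60")
})

test_that("the within-sample restriction suppresses cross-sample matches", {
  cfg <- small_config(seed = 51)
  ctg <- generate_contigs(cfg)
  pl <- plant_crispr_arrays(ctg$bacterial, ctg$viral, n_arrays = 3,
                            seed = 51)
  # move every viral contig to a sample that does not exist in bacteria
  viral_moved <- ctg$viral
  viral_moved$sample_id <- "S999"
  res <- find_crispr_interactions(pl$bacterial, viral_moved)
  expect_equal(nrow(res$interactions), 0)
})

test_that("interaction summary collapses within samples, counts across", {
  pairs <- data.frame(
    sample_id = c("S1", "S1", "S1", "S2", "S3"),
    virus_taxon = "crAss-like phage",
    host_taxon = "Ruminococcus spp",
    stringsAsFactors = FALSE)
  s <- summarize_interactions(pairs)
  expect_equal(nrow(s), 1)
  expect_equal(s$supporting_samples, 3)
  expect_equal(s$supporting_spacers, 5)
  empty <- summarize_interactions(NULL)
  expect_equal(nrow(empty), 0)
})

test_that("planted interactions are recovered exactly across seeds", {
  for (seed in c(101, 202, 303, 404, 505)) {
    cfg <- small_config(seed = seed)
    ctg <- generate_contigs(cfg)
    pl <- plant_crispr_arrays(ctg$bacterial, ctg$viral, n_arrays = 4,
                              repeats_per_array = 3, seed = seed)
    res <- find_crispr_interactions(pl$bacterial, ctg$viral)
    got <- unique(res$interactions[, c("virus_taxon", "host_taxon")])
    want <- unique(data.frame(virus_taxon = pl$pairs$viral_contig,
                              host_taxon = pl$pairs$bacterial_contig,
                              stringsAsFactors = FALSE))
    expect_equal(nrow(got), nrow(want), info = paste("seed", seed))
    expect_setequal(paste(got$virus_taxon, got$host_taxon),
                    paste(want$virus_taxon, want$host_taxon))
  }
})
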