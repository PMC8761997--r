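# Stage 3: taxonomic annotation of the identified viral contigs.
#
# Runs the three-tier cascade (nucleotide best hit -> crAss-like signature
# -> ORF voting) on the alignment evidence from stage 1 and writes the
# assignment table.

source("analysis/00_config.R")

viral_ids <- readLines(file.path(RESULTS_DIR, "viral_ids.txt"))
viral_seq <- read_fasta(file.path(FIXTURE_DIR, "viral_contigs.fasta"))
viral_seq <- viral_seq[names(viral_seq) %in% viral_ids]
contigs <- data.frame(id = names(viral_seq),
                      length = nchar(unname(viral_seq)),
                      stringsAsFactors = FALSE)
nt_hits <- read_alignment(file.path(FIXTURE_DIR, "nt_hits.tsv"))
taxmap <- read_tsv(file.path(FIXTURE_DIR, "taxmap.tsv"))

assign <- cascade_annotate(contigs, nt_hits, taxmap)
write_tsv(assign, file.path(RESULTS_DIR, "taxonomy_assignments.tsv"))

cat("Assignments by tier:\n")
print(table(assign$tier))
cat("\nFamily composition:\n")
print(sort(table(assign$family), decreasing = TRUE))
truth <- read_tsv(file.path(FIXTURE_DIR, "ground_truth.tsv"))
acc <- mean(assign$family ==
            truth$family[match(assign$contig_id, truth$contig_id)])
cat("\nFamily-level agreement with ground truth:",
    sprintf("%.1f%%", 100 * acc), "\n")
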