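# Stage 1: generate the synthetic fixture bundle and cohort.
#
# Writes contig FASTA files, classifier evidence, taxonomy evidence, depth
# tables, cohort metadata and abundance, and the ground truth (which no
# later stage reads) under results/fixtures/.

source("analysis/00_config.R")

paths <- simulate_bundle(sequence_config(), FIXTURE_DIR, preset = "perfect")

coh <- generate_cohort_abundance(cohort_config())
write_matrix_tsv(coh$bacterial, file.path(FIXTURE_DIR,
                                          "bacterial_abundance.tsv"))

md <- coh$metadata
cat("Synthetic cohort:", nrow(md), "samples\n")
print(table(md$phenotype, md$batch))
cat("\nPer-disease case/control designs:\n")
ra <- md[md$batch %in% 1:3 & md$phenotype %in% c("HC", "RA"), ]
sle <- md[md$batch %in% c(2, 3, 5) & md$phenotype %in% c("HC", "SLE"), ]
ms <- md[md$batch == 4 & md$phenotype %in% c("HC", "MS"), ]
cat(sprintf("  RA : %d cases / %d controls (batches 1-3)\n",
            sum(ra$phenotype == "RA"), sum(ra$phenotype == "HC")))
cat(sprintf("  SLE: %d cases / %d controls (batches 2,3,5)\n",
            sum(sle$phenotype == "SLE"), sum(sle$phenotype == "HC")))
cat(sprintf("  MS : %d cases / %d controls (batch 4)\n",
            sum(ms$phenotype == "MS"), sum(ms$phenotype == "HC")))
cat("\nFixtures written:\n")
for (p in paths) cat("  ", p, "\n")
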