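# Stage 4: abundance quantification and QC.
#
# Contig depths from stage 1 are normalized by per-sample total sequenced
# length and aggregated to family level; the cohort-level family matrix then
# passes clade QC and the PCA outlier screen.

source("analysis/00_config.R")

depth <- read_tsv(file.path(FIXTURE_DIR, "depth.tsv"))
assign <- read_tsv(file.path(RESULTS_DIR, "taxonomy_assignments.tsv"))
taxo <- stats::setNames(assign$family, assign$contig_id)

# per-sample totals mirror the generator's deterministic stream
dep <- generate_depths(
  data.frame(id = depth$contig_id, sample_id = depth$sample_id),
  sequence_config())
fam <- normalize_viral(depth, dep$total_bases, taxo)
write_matrix_tsv(fam, file.path(RESULTS_DIR, "family_abundance_bundle.tsv"))
cat("Bundle-level family abundance:", nrow(fam), "samples x",
    ncol(fam), "families\n")

# cohort-level matrix for the association stage
coh <- generate_cohort_abundance(cohort_config())
qc <- clade_qc(coh$viral, coh$metadata$batch, mode = "viral")
cat("\nViral clade QC: retained", length(qc), "of", ncol(coh$viral),
    "families:\n  ", paste(qc, collapse = ", "), "\n")
bqc <- clade_qc(coh$bacterial, coh$metadata$batch, mode = "bacterial")
cat("Bacterial clade QC: retained", length(bqc), "of",
    ncol(coh$bacterial), "clades\n")
out <- pca_outliers(log_transform(coh$viral))
cat("PCA outlier screen flagged", length(out), "sample(s)",
    if (length(out)) paste0("(", paste(out, collapse = ", "), ")") else "",
    "\n")
writeLines(qc, file.path(RESULTS_DIR, "qc_viral_clades.txt"))
writeLines(bqc, file.path(RESULTS_DIR, "qc_bacterial_clades.txt"))
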