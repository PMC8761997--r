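# Stage 6: CRISPR-spacer virus-host interaction calling.
#
# Scans the non-viral contigs for repeat-spacer arrays, matches spacers
# against viral contigs of the same sample, and summarizes unique
# virus-host pairs across samples; compares the calls with the planted
# ground truth.

source("analysis/00_config.R")

cfg <- sequence_config()
ctg <- generate_contigs(cfg)
planted <- plant_crispr_arrays(
  ctg$bacterial, ctg$viral,
  n_arrays = max(1L, cfg$n_bacterial_contigs %/% 2L), seed = cfg$seed)

res <- find_crispr_interactions(planted$bacterial, ctg$viral)
write_tsv(res$interactions, file.path(RESULTS_DIR, "interactions.tsv"))
if (!is.null(res$matches)) {
  write_tsv(res$matches, file.path(RESULTS_DIR, "spacer_matches.tsv"))
}

n_arrays <- sum(lengths(res$arrays))
n_spacers <- if (is.null(res$matches)) 0L else nrow(res$matches)
cat("CRISPR arrays detected:", n_arrays,
    " spacers:", n_spacers,
    " matched:", if (n_spacers) sum(!is.na(res$matches$contig_id)) else 0,
    "\n")
cat("Unique virus-host interactions:", nrow(res$interactions), "\n")
print(res$interactions, row.names = FALSE)

want <- unique(paste(planted$pairs$viral_contig,
                     planted$pairs$bacterial_contig))
got <- paste(res$interactions$virus_taxon, res$interactions$host_taxon)
cat("\nPlanted pairs recovered exactly:", setequal(got, want), "\n")
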