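# Stage 5: association statistics.
#
# Case-control logistic regression per QC-passed viral family and disease
# (with the published batch designs), a combined analysis, a random-effects
# meta-analysis across the three diseases (SLE restricted to batch 5 so the
# control sets stay disjoint), and the virus-bacterium association scan.

source("analysis/00_config.R")

coh <- generate_cohort_abundance(cohort_config())
md <- coh$metadata
vlog <- log_transform(coh$viral)
qc <- readLines(file.path(RESULTS_DIR, "qc_viral_clades.txt"))
bqc <- readLines(file.path(RESULTS_DIR, "qc_bacterial_clades.txt"))

## per-disease and combined case-control tests
cc <- list()
for (clade in qc) {
  for (dz in c("RA", "SLE", "MS", "combined")) {
    r <- suppressWarnings(case_control_test(vlog[, clade], md, dz))
    r$unit <- clade
    cc[[length(cc) + 1L]] <- r
  }
}
cc <- do.call(rbind, cc)
write_tsv(cc, file.path(RESULTS_DIR, "case_control.tsv"))

bonf <- bonferroni_threshold(0.05, length(qc))
cat(sprintf("Case-control tests: %d clades x 4 designs; Bonferroni %.2g\n",
            length(qc), bonf))
sig <- cc[!is.na(cc$p) & cc$p < bonf, ]
cat("Significant at Bonferroni:\n")
print(sig[, c("unit", "model_label", "effect", "se", "p")], row.names = FALSE)

## random-effects meta-analysis of the planted crAss-like phage signal
per_dz <- lapply(c("RA", "MS"), function(dz) {
  suppressWarnings(case_control_test(vlog[, "crAss-like phage"], md, dz))
})
sle5 <- suppressWarnings(case_control_test(vlog[, "crAss-like phage"], md,
                                           "SLE", batch_subset = 5))
eff <- c(vapply(per_dz, `[[`, numeric(1), "effect"), sle5$effect)
ses <- c(vapply(per_dz, `[[`, numeric(1), "se"), sle5$se)
meta <- meta_random_effects(eff, ses)
cat(sprintf(paste0("\ncrAss-like phage meta-analysis (RA, MS, SLE@batch5):",
                   "\n  pooled effect %.3f (SE %.3f), P = %.3g,",
                   " tau2 = %.4f, Q = %.2f, P_Q = %.2f\n"),
            meta$pooled_effect, meta$pooled_se, meta$p, meta$tau2,
            meta$Q, meta$p_Q))
write_tsv(data.frame(pooled_effect = meta$pooled_effect,
                     pooled_se = meta$pooled_se, p = meta$p,
                     tau2 = meta$tau2, Q = meta$Q, p_Q = meta$p_Q),
          file.path(RESULTS_DIR, "meta_crass.tsv"))

## virus-bacterium association scan with bacterial PCs as covariates
blog <- log_transform(coh$bacterial[, bqc, drop = FALSE])
vb <- virus_bacterium_test(vlog[, qc, drop = FALSE], blog, md)
write_tsv(vb, file.path(RESULTS_DIR, "virus_bacterium.tsv"))
cat(sprintf("\nVirus-bacterium scan: %d pairs; Bonferroni %.2g\n",
            nrow(vb), attr(vb, "bonferroni")))
top <- vb[order(vb$p)[1:3], ]
cat("Top pairs:\n")
print(top[, c("virus", "bacterium", "effect", "se", "p", "fdr")],
      row.names = FALSE)
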