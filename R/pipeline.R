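#' Run the whole synthetic-cohort pipeline end to end
#'
#' Orchestrates simulate -> identify -> classify -> quantify -> associate ->
#' crispr on a synthetic fixture bundle, writing each stage's plain-text
#' outputs under `out_dir` and returning a run manifest with per-file
#' content digests.  Deterministic stages reproduce identical digests when
#' re-run with the same config.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @param preset Evidence preset for the simulate stage.
#' @return A `run_manifest` list: config snapshot, seed, per-stage file
#'   digests, stage summaries and accumulated warnings.
#' @export
run_all <- function(config, out_dir, preset = "perfect") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, config = config,
                   started = format(Sys.time()), stages = list(),
                   warnings = character(0))
  note <- function(stage, files, info = list()) {
    manifest$stages[[stage]] <<- list(
      files = files,
      digests = tools::md5sum(files),
      info = info)
  }

  # --- simulate -------------------------------------------------------
  ctg <- generate_contigs(config)
  planted <- plant_crispr_arrays(
    ctg$bacterial, ctg$viral,
    n_arrays = max(1L, config$n_bacterial_contigs %/% 2L),
    seed = config$seed)
  ctg$bacterial <- planted$bacterial
  ctg$truth$planted_interactions <- planted$pairs
  contigs <- rbind(ctg$viral, ctg$bacterial)
  evidence <- generate_evidence(contigs, ctg$truth, config, preset = preset)
  tax_ev <- generate_taxonomy_evidence(ctg$viral, ctg$truth)
  dep <- generate_depths(ctg$viral, config)
  coh <- generate_cohort_abundance(config)
  sim_files <- c(file.path(out_dir, "evidence.tsv"),
                 file.path(out_dir, "metadata.tsv"))
  write_tsv(evidence, sim_files[1])
  write_tsv(coh$metadata, sim_files[2])
  note("simulate", sim_files,
       list(n_viral = nrow(ctg$viral), n_bacterial = nrow(ctg$bacterial),
            n_samples = nrow(coh$metadata)))

  # --- identify -------------------------------------------------------
  idf <- identify_viral_contigs(contigs, evidence)
  f <- file.path(out_dir, "audit.tsv")
  write_tsv(idf$audit, f)
  note("identify", f,
       list(n_in = nrow(contigs), n_viral = length(idf$viral_ids)))
  if (!length(idf$viral_ids)) {
    stop("stage identify: no viral contigs recovered", call. = FALSE)
  }
  viral <- contigs[contigs$id %in% idf$viral_ids, , drop = FALSE]
  nonviral <- contigs[!contigs$id %in% idf$viral_ids, , drop = FALSE]

  # --- classify -------------------------------------------------------
  assign <- cascade_annotate(viral, tax_ev$nt_hits, tax_ev$taxmap)
  f <- file.path(out_dir, "taxonomy.tsv")
  write_tsv(assign, f)
  note("classify", f,
       list(n_classified = sum(assign$family != "unclassified")))

  # --- quantify -------------------------------------------------------
  taxo <- stats::setNames(assign$family, assign$contig_id)
  dep_sub <- dep$depth[dep$depth$contig_id %in% viral$id, , drop = FALSE]
  fam_abund <- normalize_viral(dep_sub, dep$total_bases, taxo)
  f <- file.path(out_dir, "family_abundance.tsv")
  write_matrix_tsv(fam_abund, f)
  note("quantify", f, list(n_families = ncol(fam_abund)))

  # --- associate ------------------------------------------------------
  md <- coh$metadata
  if (!all(c("phenotype", "age", "sex", "batch", "total_bases") %in%
           names(md))) {
    missing <- setdiff(c("phenotype", "age", "sex", "batch", "total_bases"),
                       names(md))
    stop("stage associate: missing metadata column ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  vlog <- log_transform(coh$viral)
  qc <- clade_qc(coh$viral, md$batch, mode = "viral")
  res <- do.call(rbind, lapply(qc, function(clade) {
    r <- case_control_test(vlog[, clade], md, "combined")
    r$unit <- clade
    r
  }))
  f <- file.path(out_dir, "case_control.tsv")
  write_tsv(res, f)
  note("associate", f, list(n_clades = length(qc)))

  # --- crispr ---------------------------------------------------------
  cr <- find_crispr_interactions(nonviral, viral)
  f <- file.path(out_dir, "interactions.tsv")
  write_tsv(cr$interactions, f)
  note("crispr", f, list(n_interactions = nrow(cr$interactions)))

  manifest$finished <- format(Sys.time())
  manifest$truth <- ctg$truth
  class(manifest) <- "run_manifest"
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("pipeline run (seed ", x$seed, ")\n", sep = "")
  for (st in names(x$stages)) {
    info <- x$stages[[st]]$info
    cat("  ", st, ": ",
        paste(names(info), unlist(info), sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
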