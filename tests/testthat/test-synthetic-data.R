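test_that("config validation rejects impossible settings", {
  expect_error(sim_config(n_viral_contigs = -1), "counts")
  expect_error(sim_config(zero_inflation = 1), "zero_inflation")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(coabundance_pairs = data.frame(
    viral_clade = "Podoviridae", bacterial_clade = "Faecalibacterium_spp",
    rho = 1)), "strictly inside")
})

test_that("circular fraction controls exact terminal repeats", {
  cfg <- small_config(circular_fraction = 1)
  ctg <- generate_contigs(cfg)
  for (s in ctg$viral$sequence) {
    n <- nchar(s)
    expect_identical(substr(s, 1, 55), substr(s, n - 54, n))
  }
  cfg0 <- small_config(circular_fraction = 0)
  ctg0 <- generate_contigs(cfg0)
  for (s in ctg0$viral$sequence) {
    n <- nchar(s)
    expect_false(substr(s, 1, 50) == substr(s, n - 49, n))
  }
  expect_true(all(grepl("^[ACGT]+$", ctg$viral$sequence)))
  expect_true(all(ctg$bacterial$length >= 5000))
})

test_that("identical seed gives byte-identical fixture bundles", {
  cfg <- small_config(seed = 13)
  d1 <- file.path(tempdir(), "bundle_a")
  d2 <- file.path(tempdir(), "bundle_b")
  p1 <- simulate_bundle(cfg, d1)
  p2 <- simulate_bundle(cfg, d2)
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]), info = k)
  }
})

test_that("planted arrays have k-1 spacers copied from same-sample contigs", {
  cfg <- small_config(seed = 21)
  ctg <- generate_contigs(cfg)
  pl <- plant_crispr_arrays(ctg$bacterial, ctg$viral, n_arrays = 4,
                            repeats_per_array = 3, seed = 5)
  expect_equal(nrow(pl$pairs), 4)
  # every spacer-bearing pair references contigs that exist and share sample
  for (i in seq_len(nrow(pl$pairs))) {
    b <- pl$pairs$bacterial_contig[i]
    v <- pl$pairs$viral_contig[i]
    expect_true(b %in% ctg$bacterial$id)
    expect_true(v %in% ctg$viral$id)
    expect_identical(
      ctg$bacterial$sample_id[ctg$bacterial$id == b],
      ctg$viral$sample_id[ctg$viral$id == v])
  }
  # planted arrays: spacers are exact substrings of the source viral contig
  mod <- pl$bacterial$sequence[match(pl$pairs$bacterial_contig[1],
                                     pl$bacterial$id)]
  arrays <- detect_crispr_arrays(mod)
  expect_gte(length(arrays), 1)
  src <- ctg$viral$sequence[ctg$viral$id == pl$pairs$viral_contig[1]]
  for (sp in arrays[[1]]$spacers$sequence) {
    expect_true(grepl(sp, src, fixed = TRUE))
  }
})

test_that("plant_crispr_arrays degenerate and error cases", {
  cfg <- small_config(seed = 22)
  ctg <- generate_contigs(cfg)
  out <- plant_crispr_arrays(ctg$bacterial, ctg$viral, n_arrays = 0)
  expect_identical(out$bacterial, ctg$bacterial)
  expect_equal(nrow(out$pairs), 0)
  expect_error(plant_crispr_arrays(ctg$bacterial, ctg$viral,
                                   repeats_per_array = 1),
               ">= 2")
  tiny_viral <- data.frame(id = "v1", sequence = "ACGT", length = 4L,
                           circular = FALSE, sample_id = "S001")
  expect_error(plant_crispr_arrays(ctg$bacterial, tiny_viral, n_arrays = 1),
               "shorter than")
})

test_that("perfect evidence lets identification recover ground truth", {
  cfg <- small_config(seed = 31)
  ctg <- generate_contigs(cfg)
  contigs <- rbind(ctg$viral, ctg$bacterial)
  ev <- generate_evidence(contigs, ctg$truth, cfg, preset = "perfect")
  got <- identify_viral_contigs(contigs, ev)
  expect_setequal(got$viral_ids, ctg$truth$true_viral_ids)
})

test_that("adversarial evidence plants a contamination-rejected viral", {
  cfg <- small_config(seed = 32)
  ctg <- generate_contigs(cfg)
  contigs <- rbind(ctg$viral, ctg$bacterial)
  ev <- generate_evidence(contigs, ctg$truth, cfg, preset = "adversarial")
  planted <- ev[ev$bacterial_ortholog_hits == 6 & ev$viral_family_hits == 100, ]
  expect_equal(nrow(planted), 1)
  expect_false(contamination_filter(planted$bacterial_ortholog_hits,
                                    planted$viral_family_hits))
  ev2 <- generate_evidence(contigs, ctg$truth, cfg, preset = "adversarial")
  expect_identical(ev, ev2)  # deterministic under fixed seed
})

test_that("default cohort reproduces the study design counts", {
  coh <- generate_cohort_abundance(null_cohort_config(1))
  md <- coh$metadata
  expect_equal(nrow(md), 476)
  expect_equal(as.integer(table(md$phenotype)[c("HC", "RA", "SLE", "MS")]),
               c(289L, 111L, 47L, 29L))
  # per-disease case/control counts within the design batch subsets
  ra <- md[md$batch %in% 1:3 & md$phenotype %in% c("HC", "RA"), ]
  expect_equal(sum(ra$phenotype == "RA"), 111)
  expect_equal(sum(ra$phenotype == "HC"), 111)
  sle <- md[md$batch %in% c(2, 3, 5) & md$phenotype %in% c("HC", "SLE"), ]
  expect_equal(sum(sle$phenotype == "SLE"), 47)
  expect_equal(sum(sle$phenotype == "HC"), 201)
  ms <- md[md$batch == 4 & md$phenotype %in% c("HC", "MS"), ]
  expect_equal(sum(ms$phenotype == "MS"), 29)
  expect_equal(sum(ms$phenotype == "HC"), 74)
})

test_that("co-abundant pair correlates on the log scale", {
  cfg <- sim_config(seed = 41, n_bacterial_clades = 5L,
                    zero_inflation = 0,
                    planted_effects = no_effects(),
                    coabundance_pairs = data.frame(
                      viral_clade = "Podoviridae",
                      bacterial_clade = "Faecalibacterium_spp",
                      rho = 0.9))
  coh <- generate_cohort_abundance(cfg)
  r <- cor(log10(coh$viral[, "Podoviridae"]),
           log10(coh$bacterial[, "Faecalibacterium_spp"]))
  expect_gt(r, 0.8)
})

test_that("non-positive-definite co-abundance structure is an error", {
  cfg <- sim_config(seed = 42, n_bacterial_clades = 5L,
                    planted_effects = no_effects(),
                    coabundance_pairs = data.frame(
                      viral_clade = c("Podoviridae", "Myoviridae"),
                      bacterial_clade = "Faecalibacterium_spp",
                      rho = c(0.95, 0.95)))
  expect_error(generate_cohort_abundance(cfg), "positive definite")
})
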