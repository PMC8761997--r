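test_that("standardization is exact, idempotent and affine-invariant", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  z <- standardize(rnorm(50))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(standardize(z), z, tolerance = 1e-12)
  x <- rnorm(30)
  expect_equal(standardize(3 * x - 7), standardize(x), tolerance = 1e-12)
  expect_error(standardize(rep(2, 10)), "constant")
})

test_that("logistic fit agrees with an independent IRLS implementation", {
  irls_logistic <- function(X, y, tol = 1e-12) {
    beta <- rep(0, ncol(X))
    for (i in 1:100) {
      eta <- X %*% beta
      mu <- 1 / (1 + exp(-eta))
      W <- as.numeric(mu * (1 - mu))
      zv <- eta + (y - mu) / W
      beta_new <- solve(crossprod(X, X * W), crossprod(X, W * zv))
      if (max(abs(beta_new - beta)) < tol) return(as.numeric(beta_new))
      beta <- beta_new
    }
    as.numeric(beta)
  }
  set.seed(10)
  n <- 80
  X <- cbind(1, rnorm(n), runif(n))
  y <- rbinom(n, 1, plogis(X %*% c(-0.5, 1, 0.8)))
  ref <- irls_logistic(X, y)
  fit <- glm(y ~ X[, 2] + X[, 3], family = binomial())
  expect_equal(unname(coef(fit)), ref, tolerance = 1e-6)
})

test_that("case-control test is centred at zero under label permutation", {
  coh <- generate_cohort_abundance(null_cohort_config(17))
  vlog <- log_transform(coh$viral)
  x <- vlog[, "crAss-like phage"]
  set.seed(2)
  effs <- replicate(40, {
    md <- coh$metadata
    md$phenotype <- sample(md$phenotype)
    case_control_test(x, md, "combined")$effect
  })
  expect_lt(abs(mean(effs)), 0.08)
})

test_that("effect estimates are invariant to affine abundance rescaling", {
  coh <- generate_cohort_abundance(effect_cohort_config(23, -0.5))
  vlog <- log_transform(coh$viral)
  x <- vlog[, "crAss-like phage"]
  r1 <- case_control_test(x, coh$metadata, "combined")
  r2 <- case_control_test(5 * x + 3, coh$metadata, "combined")
  expect_equal(r1$effect, r2$effect, tolerance = 1e-9)
  expect_equal(r1$p, r2$p, tolerance = 1e-9)
})

test_that("per-disease designs use the published batch subsets", {
  coh <- generate_cohort_abundance(null_cohort_config(29))
  vlog <- log_transform(coh$viral)
  x <- vlog[, "Podoviridae"]
  ra <- case_control_test(x, coh$metadata, "RA")
  expect_equal(c(ra$n_case, ra$n_control), c(111, 111))
  sle <- case_control_test(x, coh$metadata, "SLE")
  expect_equal(c(sle$n_case, sle$n_control), c(47, 201))
  # single-batch designs drop the constant batch covariate with a warning
  expect_warning(ms <- case_control_test(x, coh$metadata, "MS"),
                 "constant covariate")
  expect_equal(c(ms$n_case, ms$n_control), c(29, 74))
  # SLE restricted to batch 5 (the meta-analysis design, disjoint controls)
  expect_warning(sle5 <- case_control_test(x, coh$metadata, "SLE",
                                           batch_subset = 5),
                 "constant covariate")
  expect_equal(sle5$n_case, 27)
  expect_equal(sle5$n_control, 104)
})

test_that("perfect separation is flagged, never silently converged", {
  md <- toy_metadata(40, rep(c("HC", "RA"), each = 20))
  x <- ifelse(md$phenotype == "RA", 5, -5) + rnorm(40, sd = 0.01)
  r <- suppressWarnings(case_control_test(x, md, "RA", batch_subset = 1:2))
  expect_true(r$separation)
  expect_true(is.na(r$p))
})

test_that("subset filters implement the sub-analysis scheme", {
  md <- toy_metadata(60, rep(c("HC", "RA"), each = 30), seed = 3)
  n_male <- sum(md$sex == "male")
  f <- subset_filters(md, "females_only")
  expect_equal(nrow(f), nrow(md) - n_male)
  expect_identical(subset_filters(f, "females_only"), f)  # idempotent
  u <- subset_filters(md, "untreated")
  expect_false(any(u$treated[u$phenotype != "HC"]))
  expect_true(all(md$sample_id[md$phenotype == "HC"] %in% u$sample_id))
  no_flags <- md
  no_flags[, c("antibiotics", "ppi", "steroid", "treated")] <- FALSE
  no_flags$new_onset <- no_flags$phenotype != "HC"
  for (fn in c("new_onset_only", "no_antibiotics", "no_ppi", "no_steroid",
               "untreated")) {
    expect_identical(subset_filters(no_flags, fn), no_flags, info = fn)
  }
  expect_error(subset_filters(md, "bogus"), "unknown filter")
})

test_that("within-case contrast recovers a planted treatment shift", {
  set.seed(31)
  diffs <- replicate(60, {
    md <- toy_metadata(100, rep("RA", 100), seed = sample.int(1e6, 1))
    raw <- rnorm(100) + 0.5 * md$treated
    est <- within_case_test(raw, md, "treated_vs_untreated")$effect
    # the model standardizes internally, so the estimand is the planted
    # 0.5 raw-unit shift divided by this replicate's total SD
    est - 0.5 / sd(raw)
  })
  expect_equal(mean(diffs), 0, tolerance = 0.1)
})

test_that("within-case contrast rejects degenerate designs", {
  md <- toy_metadata(30, rep("RA", 30))
  md$treated <- TRUE
  expect_error(within_case_test(rnorm(30), md, "treated_vs_untreated"),
               "single level")
  md2 <- toy_metadata(6, rep("RA", 6))
  expect_error(within_case_test(rnorm(6), md2, "treated_vs_untreated"),
               "fewer samples")
  md3 <- toy_metadata(30, rep(c("HC", "RA"), 15))
  expect_error(within_case_test(rnorm(30), md3, "treated_vs_untreated"),
               "cases only")
})

test_that("age/sex test reports both terms and drops aliased covariates", {
  cfg <- null_cohort_config(37)
  coh <- generate_cohort_abundance(cfg)
  vlog <- log_transform(coh$viral)
  res <- age_sex_test(vlog, coh$metadata)
  expect_setequal(unique(res$term), c("age", "sex_male"))
  expect_equal(attr(res, "bonferroni"), 0.05 / 8)
  md_const <- coh$metadata
  md_const$age <- 50
  expect_warning(res2 <- age_sex_test(vlog, md_const), "age")
  expect_false("age" %in% res2$term)
})

test_that("virus-bacterium scan ranks a planted co-abundant pair first", {
  cfg <- sim_config(seed = 43, n_bacterial_clades = 20L,
                    zero_inflation = 0,
                    planted_effects = no_effects(),
                    coabundance_pairs = data.frame(
                      viral_clade = "Podoviridae",
                      bacterial_clade = "Faecalibacterium_spp",
                      rho = 0.6))
  coh <- generate_cohort_abundance(cfg)
  res <- virus_bacterium_test(log_transform(coh$viral),
                              log_transform(coh$bacterial),
                              coh$metadata)
  expect_equal(nrow(res), 8 * 20)
  top <- res[which.min(res$p), ]
  expect_identical(top$virus, "Podoviridae")
  expect_identical(top$bacterium, "Faecalibacterium_spp")
  expect_lt(top$fdr, 0.05)
  expect_true(all(res$fdr >= res$p))
  expect_equal(attr(res, "bonferroni"), 0.05 / 160)
})

test_that("single-pair FDR equals the raw p-value", {
  cfg <- sim_config(seed = 44, n_bacterial_clades = 1L,
                    planted_effects = no_effects(),
                    coabundance_pairs = no_pairs())
  coh <- generate_cohort_abundance(cfg)
  res <- virus_bacterium_test(log_transform(coh$viral[, "Myoviridae",
                                                      drop = FALSE]),
                              log_transform(coh$bacterial),
                              coh$metadata, n_pcs = 0)
  expect_equal(res$fdr, res$p)
})

test_that("interaction test reports the product term and its guards", {
  cfg <- sim_config(seed = 45, n_bacterial_clades = 2L,
                    planted_effects = no_effects(),
                    coabundance_pairs = no_pairs())
  coh <- generate_cohort_abundance(cfg)
  r <- interaction_test(log_transform(coh$viral)[, "Podoviridae"],
                        log_transform(coh$bacterial)[, 1],
                        coh$metadata, "RA")
  expect_true(is.finite(r$p))
  expect_identical(r$model_label, "interaction_RA")
  md_no_cases <- coh$metadata
  md_no_cases$phenotype[md_no_cases$phenotype == "MS"] <- "HC"
  expect_error(interaction_test(log_transform(coh$viral)[, 1],
                                log_transform(coh$bacterial)[, 1],
                                md_no_cases, "MS"),
               "no cases")
})

test_that("BH adjustment matches the step-up formula oracle", {
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    pmin(adj, 1)[order(o)]
  }
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)),
               bh_oracle(c(0.01, 0.02, 0.03, 0.04)))
  set.seed(12)
  for (i in 1:25) {
    p <- runif(sample(1:60, 1))
    expect_equal(bh_fdr(p), bh_oracle(p))
    adj <- bh_fdr(p)
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
  expect_error(bh_fdr(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("Bonferroni thresholds reproduce the published arithmetic", {
  expect_equal(bonferroni_threshold(0.05, 8), 0.00625)
  # agreement with the printed 2-significant-figure values to half a unit
  # in the last printed digit
  expect_lte(abs(bonferroni_threshold(0.05, 8) - 0.0063), 5e-5)
  expect_lte(abs(bonferroni_threshold(0.05, 8 * 802) - 7.8e-6), 5e-8)
  expect_error(bonferroni_threshold(0.05, 0), ">= 1")
})
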