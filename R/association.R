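#' Z-score standardization
#'
#' Centers and scales to unit sample SD (n - 1 denominator).  Standardization
#' is always computed within the analysis sample set, i.e. after any batch or
#' phenotype subsetting.
#'
#' @param x Numeric vector with at least two distinct finite values.
#' @return Numeric vector with mean 0, SD 1.
#' @export
standardize <- function(x) {
  if (length(unique(x[is.finite(x)])) < 2L) {
    stop("cannot standardize a constant vector", call. = FALSE)
  }
  (x - mean(x)) / stats::sd(x)
}

# Covariate frame shared by the association models.  total sequenced length
# is rescaled to Gb so design matrices stay well conditioned.
assoc_covariates <- function(metadata, age2 = TRUE) {
  df <- data.frame(
    sex = factor(metadata$sex),
    age = metadata$age,
    total_gb = metadata$total_bases / 1e9,
    batch = factor(metadata$batch))
  if (age2) df$age2 <- metadata$age^2
  df
}

# Drop constant columns / single-level factors (aliased in the subset) with
# a warning; returns the usable covariate terms.
usable_terms <- function(df) {
  ok <- vapply(df, function(x) {
    if (is.factor(x)) nlevels(droplevels(x)) > 1L else
      length(unique(x)) > 1L
  }, logical(1))
  if (any(!ok)) {
    warning("dropping constant covariate(s): ",
            paste(names(df)[!ok], collapse = ", "))
  }
  names(df)[ok]
}

# Default batch subset per case-control design.
design_batches <- function(case_label) {
  switch(case_label,
         RA = 1:3,
         SLE = c(2, 3, 5),
         MS = 4,
         combined = NULL,
         stop("unknown case label: ", case_label, call. = FALSE))
}

#' Age and sex association test for viral clades
#'
#' Ordinary least squares of log abundance on age, sex, phenotype,
#' sequencing batch and total sequenced length, reporting the age and sex
#' coefficients per clade.  The companion Bonferroni threshold is
#' `0.05 / number of clades`.
#'
#' @param log_mat Samples x clades log-abundance matrix.
#' @param metadata Sample metadata aligned with the rows.
#' @return Data frame (clade, term, effect, se, p) with attribute
#'   `bonferroni` = 0.05 / number of clades.
#' @export
age_sex_test <- function(log_mat, metadata) {
  stopifnot(nrow(log_mat) == nrow(metadata))
  cov <- assoc_covariates(metadata, age2 = FALSE)
  cov$phenotype <- factor(metadata$phenotype)
  terms <- usable_terms(cov)
  out <- list()
  for (clade in colnames(log_mat)) {
    d <- cbind(y = log_mat[, clade], cov)
    fit <- stats::lm(stats::reformulate(terms, response = "y"), data = d)
    sm <- summary(fit)$coefficients
    for (term in c("age", "sexmale")) {
      if (!term %in% rownames(sm)) next
      out[[length(out) + 1L]] <- data.frame(
        clade = clade,
        term = if (term == "age") "age" else "sex_male",
        effect = sm[term, 1], se = sm[term, 2], p = sm[term, 4],
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "bonferroni") <- bonferroni_threshold(0.05, ncol(log_mat))
  res
}

#' Case-control logistic association test for one clade
#'
#' Logistic regression of case status on the standardized log abundance with
#' sex, age, age squared, sequencing batch (categorical) and total sequenced
#' length as covariates.  The sample set is healthy controls plus the chosen
#' case group, restricted to the design's sequencing batches (RA: 1-3,
#' SLE: 2, 3 and 5, MS: 4, combined: all); standardization happens within
#' that subset.  Perfect separation is flagged (`p` set to NA), never
#' silently reported as converged.
#'
#' @param log_abund Numeric log-abundance vector aligned with `metadata`
#'   rows (full cohort; subsetting happens inside).
#' @param metadata Sample metadata.
#' @param case_label "RA", "SLE", "MS" or "combined".
#' @param batch_subset Optional batch vector overriding the design default.
#' @param presence Logical: treat `log_abund` as a binary presence vector
#'   and use it unstandardized.
#' @return One-row data frame: unit, effect, se, p, n_case, n_control,
#'   model_label, separation.
#' @export
case_control_test <- function(log_abund, metadata, case_label = "combined",
                              batch_subset = NULL, presence = FALSE) {
  stopifnot(length(log_abund) == nrow(metadata))
  if (is.null(batch_subset)) batch_subset <- design_batches(case_label)
  keep_pheno <- if (case_label == "combined") {
    rep(TRUE, nrow(metadata))
  } else metadata$phenotype %in% c("HC", case_label)
  keep <- keep_pheno &
    (if (is.null(batch_subset)) TRUE else metadata$batch %in% batch_subset)
  md <- metadata[keep, , drop = FALSE]
  y <- as.integer(md$phenotype != "HC")
  if (!any(y == 1L) || !any(y == 0L)) {
    stop("subset has no cases or no controls", call. = FALSE)
  }
  x <- log_abund[keep]
  z <- if (presence) x else standardize(x)
  cov <- assoc_covariates(md)
  terms <- c("z", usable_terms(cov))
  d <- cbind(data.frame(case = y, z = z), cov)
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(stats::reformulate(terms, response = "case"),
               family = stats::binomial(), data = d),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  sm <- summary(fit)$coefficients
  # separation can converge without tripping glm's epsilon warning; a
  # log-odds beyond +-15 per SD or an exploded SE is the same pathology
  if (abs(sm["z", 1]) > 15 || sm["z", 2] > 100) separated <- TRUE
  data.frame(unit = NA_character_,
             effect = sm["z", 1], se = sm["z", 2],
             p = if (separated) NA_real_ else sm["z", 4],
             n_case = sum(y), n_control = sum(1L - y),
             model_label = paste0("case_control_", case_label),
             separation = separated,
             stringsAsFactors = FALSE)
}

#' Named sample-subset filters for sensitivity analyses
#'
#' Deterministic predicates reproducing the published sub-analysis scheme:
#' removing males, non-new-onset patients, or subjects on antibiotics,
#' proton pump inhibitors, steroids or disease treatment.
#'
#' @param metadata Sample metadata.
#' @param filter_name One of "females_only", "new_onset_only",
#'   "no_antibiotics", "no_ppi", "no_steroid", "untreated".
#' @return The filtered metadata.
#' @export
subset_filters <- function(metadata, filter_name) {
  is_case <- metadata$phenotype != "HC"
  keep <- switch(filter_name,
    females_only  = metadata$sex == "female",
    new_onset_only = !is_case | metadata$new_onset,
    no_antibiotics = !metadata$antibiotics,
    no_ppi        = !metadata$ppi,
    no_steroid    = !metadata$steroid,
    untreated     = !is_case | !metadata$treated,
    stop("unknown filter: ", filter_name, call. = FALSE))
  metadata[keep, , drop = FALSE]
}

#' Within-case contrast test
#'
#' Regression of the standardized log abundance on a within-case contrast
#' (treatment, onset timing, dichotomized disease activity, or a continuous
#' marker), adjusted for the standard covariates.
#'
#' @param log_abund Log-abundance vector aligned with `metadata` rows.
#' @param metadata Case-only sample metadata.
#' @param contrast One of "treated_vs_untreated", "new_onset_vs_not",
#'   "activity_high_vs_low", "continuous_marker".
#' @return One-row data frame (unit, effect, se, p, n, model_label).
#' @export
within_case_test <- function(log_abund, metadata,
                             contrast = c("treated_vs_untreated",
                                          "new_onset_vs_not",
                                          "activity_high_vs_low",
                                          "continuous_marker")) {
  contrast <- match.arg(contrast)
  stopifnot(length(log_abund) == nrow(metadata))
  if (any(metadata$phenotype == "HC")) {
    stop("within-case test expects cases only", call. = FALSE)
  }
  x <- switch(contrast,
    treated_vs_untreated = as.numeric(metadata$treated),
    new_onset_vs_not = as.numeric(metadata$new_onset),
    activity_high_vs_low =
      as.numeric(metadata$activity_score >
                 stats::median(metadata$activity_score, na.rm = TRUE)),
    continuous_marker = metadata$marker)
  if (length(unique(x[!is.na(x)])) < 2L) {
    stop("contrast '", contrast, "' has a single level", call. = FALSE)
  }
  z <- standardize(log_abund)
  cov <- assoc_covariates(metadata)
  terms <- c("x", usable_terms(cov))
  d <- cbind(data.frame(y = z, x = x), cov)
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) <= length(terms) + 1L) {
    stop("fewer samples than model parameters", call. = FALSE)
  }
  fit <- stats::lm(stats::reformulate(terms, response = "y"), data = d)
  sm <- summary(fit)$coefficients
  data.frame(unit = NA_character_, effect = sm["x", 1], se = sm["x", 2],
             p = sm["x", 4], n = nrow(d),
             model_label = paste0("within_case_", contrast),
             stringsAsFactors = FALSE)
}

#' Virus-bacterium association scan
#'
#' For every (viral family, bacterial clade) pair, linear regression of the
#' standardized bacterial log abundance on the standardized viral log
#' abundance with sex, age, age squared, sequencing batch, total sequenced
#' length and the top bacterial principal components as covariates.
#' Benjamini-Hochberg FDR is computed jointly across all tested pairs.
#'
#' @param viral_log Samples x viral-family log matrix.
#' @param bact_log Samples x bacterial-clade log matrix.
#' @param metadata Sample metadata aligned with the rows.
#' @param n_pcs Number of leading bacterial principal components used as
#'   covariates (default 10; reduced with a warning when the matrix rank is
#'   smaller).
#' @return Data frame (virus, bacterium, effect, se, p, fdr, n) with
#'   attribute `bonferroni` = 0.05 / number of pairs.
#' @export
virus_bacterium_test <- function(viral_log, bact_log, metadata,
                                 n_pcs = 10L) {
  stopifnot(nrow(viral_log) == nrow(metadata),
            nrow(bact_log) == nrow(metadata))
  bz <- scale(bact_log)
  keep <- !apply(is.na(bz) | is.nan(bz), 2, any)
  p <- stats::prcomp(bz[, keep, drop = FALSE], center = FALSE,
                     scale. = FALSE)
  avail <- sum(p$sdev > 1e-8)
  if (n_pcs > avail) {
    warning("reducing principal components from ", n_pcs, " to ", avail)
    n_pcs <- avail
  }
  cov <- assoc_covariates(metadata)
  if (n_pcs > 0) {
    pcs <- p$x[, seq_len(n_pcs), drop = FALSE]
    colnames(pcs) <- paste0("PC", seq_len(n_pcs))
    cov <- cbind(cov, as.data.frame(pcs))
  }
  terms <- c("v", usable_terms(cov))
  out <- list()
  for (vf in colnames(viral_log)) {
    v <- standardize(viral_log[, vf])
    for (bc in colnames(bact_log)) {
      y <- standardize(bact_log[, bc])
      d <- cbind(data.frame(y = y, v = v), cov)
      fit <- stats::lm(stats::reformulate(terms, response = "y"), data = d)
      sm <- summary(fit)$coefficients
      out[[length(out) + 1L]] <- data.frame(
        virus = vf, bacterium = bc,
        effect = sm["v", 1], se = sm["v", 2], p = sm["v", 4],
        n = nrow(d), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$fdr <- bh_fdr(res$p)
  attr(res, "bonferroni") <- bonferroni_threshold(0.05, nrow(res))
  res
}

#' Disease-specific virus-bacterium interaction test
#'
#' Adds a virus x disease-indicator product term to the virus-bacterium
#' regression and reports the product coefficient.
#'
#' @param viral_log,bact_log Log-abundance vectors for one pair, aligned
#'   with `metadata` rows.
#' @param metadata Sample metadata.
#' @param disease Disease label defining the indicator ("RA", "SLE", "MS");
#'   the sample set follows the disease's case-control design.
#' @return One-row data frame for the interaction coefficient.
#' @export
interaction_test <- function(viral_log, bact_log, metadata, disease) {
  batches <- design_batches(disease)
  keep <- metadata$phenotype %in% c("HC", disease) &
    metadata$batch %in% batches
  md <- metadata[keep, , drop = FALSE]
  ind <- as.numeric(md$phenotype == disease)
  if (!any(ind == 1)) stop("no cases in subset", call. = FALSE)
  if (length(unique(ind)) < 2L) {
    stop("disease indicator is constant in subset", call. = FALSE)
  }
  v <- standardize(viral_log[keep])
  y <- standardize(bact_log[keep])
  cov <- assoc_covariates(md)
  terms <- c("v", "ind", "v:ind", usable_terms(cov))
  d <- cbind(data.frame(y = y, v = v, ind = ind), cov)
  fit <- stats::lm(stats::reformulate(terms, response = "y"), data = d)
  sm <- summary(fit)$coefficients
  data.frame(unit = paste0("virus_x_", disease),
             effect = sm["v:ind", 1], se = sm["v:ind", 2],
             p = sm["v:ind", 4], n = nrow(d),
             model_label = paste0("interaction_", disease),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement.
#'
#' @param p Vector of p-values in (0, 1].
#' @return Adjusted values, same order as input.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Bonferroni significance threshold
#' @param alpha Family-wise error rate.
#' @param m Number of tests (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  alpha / m
}
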