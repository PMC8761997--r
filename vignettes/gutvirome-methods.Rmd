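---
title: "Methods: whole-gut virome case-control analysis"
author: "gutvirome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-gut virome case-control analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutvirome)
```

## Scope and problem

Whole-metagenome shotgun sequencing of stool recovers bacteriophage
sequences together with their bacterial hosts: integrated prophages and
actively infecting phages dominate, in contrast to virus-like-particle
sequencing which favors free particles.  `gutvirome` implements the
analysis downstream of assembly: deciding which contigs are viral,
assigning taxonomy, quantifying abundance, testing disease associations
with covariate adjustment, and calling virus–host interactions from CRISPR
spacers.  Everything upstream — read QC, assembly, the external
viral-sorting, virality-scoring, ortholog and protein-family searches,
and read mapping — is consumed as tables, not re-implemented.

Because individual-level cohort data of this kind are access-controlled,
the package carries a first-class synthetic-data generator whose outputs
have known ground truth.  Every stage is exercised end to end on generated
data; the generator's defaults encode the study design the package is
built around (a 476-sample cohort: 289 healthy controls, 111 rheumatoid
arthritis, 47 systemic lupus erythematosus, 29 multiple sclerosis, five
sequencing batches).

## Viral contig identification

A contig is marked **circular** when its 5' and 3' terminals share an
exact overlap of at least 50 bp (`detect_circularity()`); exact matching
is used because a similarity tolerance would introduce an arbitrary second
threshold, and assembly terminal repeats are exact by construction.
Length gates (`length_gate()`) admit linear contigs of at least 5 kbp and
circular contigs of at least 1.5 kbp, both inclusive.  Length is measured
on the untrimmed sequence (the duplicated terminal overlap is not
removed).

The **decision tree** (`classify_viral()`) accepts sorter confidence
categories 1 and 2 outright; category 3 requires a virality score of at
least 0.7; unsorted contigs require at least 0.9.  Both cutoffs are
config-exposed and inclusive.  When a category-3 contig also clears the
0.9 cutoff, the audit trail records the category-3 branch: branches are
tested in the fixed order 1/2, then 3, then high-score.

The **contamination filter** (`contamination_filter()`) rejects a
candidate when bacterial single-copy ortholog hits divided by
viral-protein-family hits exceeds 0.05 — strictly, so a ratio of exactly
0.05 is kept.  The ratio is undefined at a zero denominator; the package
rejects when ortholog hits are present without any family hits (the ratio
diverges) and keeps when both counts are zero (no evidence either way).
This is conservative toward removing bacterial contamination.

## Taxonomy

`cascade_annotate()` applies three tiers; the first that yields an
assignment wins, so exactly one tier label is recorded per contig.

1. **Nucleotide tier**: alignment hits are filtered at E-value < 10⁻¹⁰,
   identity > 95 % and query coverage ≥ 85 %, where coverage is
   `alignment_length / contig_length` of the single best HSP (no HSP
   merging — the simplest reading of contig coverage; multi-HSP
   combination rules would be a guess).  The highest bit score wins;
   ties break toward the lexicographically smallest accession for
   determinism.  A best hit to the reference crAssphage genome
   (NC_024711.1) is reported at family level as "crAss-like phage".
2. **crAss signature tier**: any protein hit between the contig's ORFs and
   the crAssphage polymerase (UGP_018) or terminase (UGP_092) at
   E < 10⁻⁵ with alignment length ≥ 350 assigns the family directly.
3. **ORF voting**: each annotated ORF contributes its best-hit family;
   contigs with fewer than two annotated ORFs are unclassified, and a
   family must hold a *strict* majority (> half of annotated ORFs) to be
   assigned.  Strict majority was chosen because contigs "without a
   majority" are a meaningful unclassified class; a plurality mode is
   available behind `vote_family(mode = "plurality")`.  Voting is
   invariant to ORF order, and adding an ORF annotated with the current
   winner can never un-assign it.

`find_orfs()` is a deliberately naive six-frame ORF finder (ATG to stop,
≥ 60 codons) provided only so synthetic fixtures can carry ORF tables; real
pipelines consume a dedicated gene predictor's output.

## Abundance

`trimmed_mean_depth()` sorts the per-base depths and keeps the sorted
ranks `floor(trim_min·L)+1` through `ceil(trim_max·L)` (defaults 0.05 and
0.95) before averaging.  This convention discards 5 % of positions at each
end on round lengths, reproduces the constant-vector behavior of the
external coverage tool, and reduces exactly to the arithmetic mean at
`trim_min = 0, trim_max = 1`.

Viral abundance divides each contig's trimmed-mean depth by the sample's
total sequenced bases and sums family members; contigs without taxonomy
aggregate to "unclassified" with a warning.  Bacterial abundance divides
per-genome read counts by genome length and renormalizes per sample and
per taxonomic level (L2 phylum through L7 species).

**Clade QC** treats any positive value as "detected" (no detection floor
is defined anywhere upstream, and the normalized scale is continuous).
Viral clades must be detected in at least one sample of *every* sequencing
batch and in ≥ 10 % of all samples; bacterial clades additionally need
≥ 20 % prevalence and a mean relative abundance strictly above 10⁻⁵.

**PCA outlier screening** flags a sample whose absolute score on any of
the first 2 principal components (centred, scaled clades) exceeds 4
component SDs.  The component count and threshold are an invented,
config-exposed criterion: outlier removal by PCA is standard but no
numeric rule is fixed by convention; 4 SD makes removals rare (a handful
per ~500 samples), matching how such screens are used in practice.

Log transformation uses `log10(value + pseudocount)` with pseudocount half
the smallest positive value of each clade — the scale-free compositional
convention — with a per-matrix fallback and warning for all-zero clades.
The presence/absence transform binarizes at value > 0 and feeds the same
logistic model, giving a normalization-independent sensitivity analysis.

## Association models

Abundance is standardized (mean 0, sample SD 1, `n−1` denominator) within
each analysis subset, *after* batch/phenotype subsetting, because every
comparison uses a different sample set.  Log-then-standardize is the
implemented order.

`case_control_test()` fits
`case ~ z(log10 abundance) + sex + age + age² + batch + total length`
by logistic regression (`stats::glm`), with batch as categorical
indicators referenced to the lowest-numbered batch and total length in Gb
for conditioning.  The per-disease designs are RA: batches 1–3
(111 cases / 111 controls at the default cohort), SLE: batches 2, 3 and 5
(47 / 201), MS: batch 4 (29 / 74); the combined analysis uses all batches.
Covariates that are constant within a subset (the batch indicator in the
single-batch MS design) are dropped with a warning.  P-values are
two-sided Wald, matching standard generalized-linear-model summaries.
Perfect separation is *flagged* (`p = NA`), never reported as converged:
the fit is marked separated when the IRLS epsilon warning fires or when
the abundance coefficient exceeds ±15 log-odds per SD or its standard
error exceeds 100 — magnitudes no real effect reaches.

`subset_filters()` implements the six sensitivity subsets (females only,
new-onset only, and removal of antibiotics / proton-pump-inhibitor /
steroid / disease-treated subjects); `within_case_test()` regresses
abundance on a within-case contrast (treatment, onset, dichotomized
activity, continuous marker) with the same covariates.

`meta_random_effects()` estimates the between-study variance τ² by
restricted maximum likelihood with the standard iterative scheme
(weights `1/(se² + τ²)`, update
`τ² ← Σw²((y−μ̂)² − se²)/Σw² + 1/Σw`), started from the
DerSimonian–Laird estimate, floored at zero, to a tolerance of 10⁻⁸
within 100 iterations (both config-exposed); non-convergence is an error
carrying the iteration trace.  Cochran's Q uses fixed-effect weights with
k−1 degrees of freedom.  With τ² forced to zero the pooled estimate is
the fixed-effect inverse-variance mean, and the restricted likelihood is
exported (`reml_loglik()`) so independent maximizers can cross-check the
iteration.  For the three-disease meta-analysis the SLE effect is
re-estimated on batch 5 only, keeping the three control sets disjoint.

`virus_bacterium_test()` regresses each bacterial clade's standardized
log abundance on each viral family's with the standard covariates plus the
top 10 principal components of the standardized log bacterial matrix
(recomputed on each analysis subset; reduced with a warning when the rank
is smaller).  Benjamini–Hochberg FDR is computed jointly across all pairs,
and the Bonferroni threshold `0.05 / n_pairs` is attached.
`interaction_test()` adds a virus × disease product term on the disease's
own design subset.  Significance conventions: Bonferroni across the 8
families for case–control (0.05/8 = 0.00625), BH across all
virus–bacterium pairs.

## CRISPR virus–host linkage

`detect_crispr_arrays()` is a seed-and-extend repeat finder in the CRT
family, applied to non-viral contigs of ≥ 5 kbp: exact 8-mer recurrences
whose spacings fit a repeat+spacer period seed candidates; aligned copies
are extended outward while per-column agreement stays ≥ 0.9; arrays are
accepted with repeat length 23–47 bp, every spacer 26–50 bp and at least
2 repeats (the detector minimum), chains split at out-of-bounds gaps, and
overlapping candidates resolve to more repeats, then longer span.  The
external detector's full heuristics are not re-created; this detector is
self-contained, deterministic and strand-symmetric, and the published
length windows are its defaults.

Spacer matching (`match_spacers()`) searches both strands of the viral
contigs *of the same sample only* — the within-sample restriction is the
biological contract (a spacer records an infection seen by that
community).  A placement passes when the matched length is ≥ 90 % of the
spacer and identity over the matched span exceeds 95 %; for a 30-bp spacer
that permits at most one mismatch over a ≥ 27-bp match.  E-value filtering
is not meaningful for ~30-bp queries without the original database
context, so the coverage/identity criterion replaces it; placements are
ranked by `matched_length − 2·mismatches` with deterministic tie-breaks
(smaller contig id, then coordinate).  Host taxonomy comes from the best
alignment hit of the CRISPR-carrying contig at E < 10⁻¹⁰, identity
> 95 %, coverage ≥ 90 %.  Interactions are deduplicated within each
sample, then counted across samples, so a pair's support is the number of
independent samples exhibiting it.

## The synthetic-data generator

What it emulates: uniform-composition contigs with exact terminal repeats
for circularity; planted CRISPR arrays whose spacers are verbatim copies
of same-sample viral subsequences (repeat lengths 25–40 and spacer lengths
30–45 are sampled strictly inside the detector windows so one-or-two-base
extension overrun cannot push a planted array out of bounds); classifier
evidence under three presets (`perfect`, `noisy`, `adversarial` — the last
plants a true viral contig with an ortholog/family ratio of 0.06, just
above the rejection cutoff); and a cohort whose per-sample per-clade
log₁₀ abundance is

```
baseline + (planted effect × disease indicator) × noise_sd
         + batch offset + age/sex terms + N(0, noise_sd²)
```

with independent zero-inflation and bivariate-Gaussian co-abundant pairs.
The batch allocation (HC 14/48/49/74/104, RA 37/37/37/0/0, SLE
0/10/10/0/27, MS 0/0/0/29/0) is the unique simple split consistent with
every per-disease case/control design count at the default cohort sizes.
Defaults chosen once: `noise_sd = 1`, `batch_sd = 0.3` (batch effects a
third of residual noise), `zero_inflation = 0.05` (family-level clades are
prevalent), planted effects of −0.476 (RA) and −0.514 (SLE) on crAss-like
phage and −0.947 (SLE) on *Podoviridae*, and a *Podoviridae* ~
*Faecalibacterium* co-abundance of ρ = 0.35.  Sequencing yields mirror the
batch-wise means (25.5, 7.8, 6.7, 7.0, 8.3 Gb); female fractions are
higher in the autoimmune groups.  Each fixture component draws from its
own stream derived from the master seed, so adding components never
perturbs earlier ones, and identical configs give byte-identical bundles.

Planting an abundance shift of `effect × noise_sd` makes the per-SD
logistic log-odds coefficient equal `effect` when the abundance is
Gaussian given case status.  **Calibration simulations therefore run under
the fully Gaussian configuration (`zero_inflation = 0`)**: zero-inflated
entries are logged at the pseudocount, far in the lower tail, which both
inflates the standardizing SD (shrinking the estimand below the planted
value) and makes the Wald test mildly anti-conservative (measured ≈ 6.6 %
rejection at a nominal 5 % with the 5 % default inflation rate, versus a
calibrated ≈ 5.2 % under the Gaussian null over 3,000 replicates).  This
is a property of applying a Gaussian-abundance logistic model to
zero-inflated data, shared by the modeled analysis itself, and is the main
caveat when reading the calibration results back to real data.

What the generator does **not** emulate: read-level error, assembly
artifacts other than terminal repeats, genuine sequence composition
(nucleotides are i.i.d. uniform; collisions with circularity or spacer
matching are rejected and resampled), real taxonomies beyond a small
synthetic namespace, compositional closure of the abundance matrices, and
correlated medication/flag structure.  Passing tests show the *decision
logic and estimators* are correct under the declared model, not that the
thresholds are optimal for real metagenomes.

## Problem sizes and runtime choices

The bundled analyses and tests use cohorts of 476 samples for all
statistical checks (1,000 null replicates for the type-I rate, 500 for
effect recovery), 20 seeded sequence bundles of 10 viral + 6 bacterial
contigs for CRISPR recovery, and compact 40 + 12-contig bundles for the
narrative drivers — sizes at which every stage's behavior is already
asymptotically stable while the full suite runs in minutes on one CPU.

## Known limitations

* "Detected" is value > 0; depth-based detection floors would need mapping
  statistics the package does not consume.
* The PCA outlier rule is an invented operationalization of a named but
  unspecified screen.
* Coverage uses the single best HSP; multi-HSP subjects are not merged.
* The CRISPR detector recreates published length windows, not the external
  tool's full heuristics; its mismatch tolerance only matters for
  non-exact arrays, which the generator does not plant.
* Wald inference is slightly anti-conservative under zero-inflation (see
  above); likelihood-ratio tests would be better calibrated but would
  depart from the modeled analysis convention.
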