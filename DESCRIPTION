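Package: gutvirome
Title: Whole-Gut Virome Profiling and Autoimmune Case-Control Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of a whole-gut-virome analysis
    workflow for shotgun metagenomes: rule-based viral contig identification
    from external classifier evidence (sorter confidence categories,
    machine-learning virality scores, bacterial single-copy-ortholog and
    viral-protein-family contamination counts), three-tier taxonomic
    annotation (nucleotide best hit, crAss-like phage signature genes,
    ORF-majority voting), trimmed-mean depth abundance quantification with
    clade QC and PCA outlier screening, covariate-adjusted case-control and
    virus-bacterium association statistics with random-effects meta-analysis,
    and CRISPR-spacer-based virus-host interaction calling. A synthetic-data
    generator with known ground truth emulates every pipeline input so each
    stage is testable without access-controlled cohort data.
License: MIT + file LICENSE
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    tools,
    methods
Encoding: UTF-8
Suggests:
    testthat (>= 3.0.0),
    metafor,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
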