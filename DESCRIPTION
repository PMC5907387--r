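Package: dogbiome
Title: Dietary-Intervention Analysis of the Canine Gut Microbiome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical toolkit and reproducible workflow for paired
    dietary-intervention studies of the dog gut microbiome. Implements
    detection-limit-aware censored log-ratio construction with the
    two-sided Gehan generalized Wilcoxon test for doubly censored data,
    two-stage Benjamini-Hochberg FDR control, prevalence-change testing,
    compositional shift analysis (Bray-Curtis/Ruzicka distances, PCoA,
    PERMANOVA, taxon-ratio tests, leave-out robustness), sparCC basis
    correlations with permutation p-values and co-abundance network
    construction, marker-gene linkage-group (mOTU) profiling with
    detection-limit estimation and unanimity-based annotation, dual-search
    lowest-common-ancestor gene annotation, rank-normalized penalized
    logistic diet classification with leave-one-out ROC estimation, and
    strain-level SNP allele-frequency distances. A synthetic-study
    generator emulates the paired two-diet, two-body-condition design so
    the full pipeline runs end-to-end with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    mclust,
    pROC,
    withr
Config/testthat/edition: 3
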