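Package: buccalclocks
Title: Buccal Methylome Predictors and Explainable Aging Clocks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds methylation-based predictors from buccal (cheek swab)
    beta-value matrices: random-forest classifiers for smoking status and
    race/ethnicity, feed-forward neural-network regressors for alcohol
    intake, body mass index and chronological age, and biology-masked
    explainable aging clocks whose hidden layers correspond to annotated
    genes and curated gene sets. Includes correlation-based CpG feature
    selection, impurity and path-integral feature attribution, gene-set and
    genomic-feature overrepresentation analysis with hypergeometric tests
    and Benjamini-Hochberg correction, PCA/silhouette batch-effect
    screening, delta-age association models, and a synthetic-cohort
    generator so the full pipeline can be exercised without restricted
    cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    pracma,
    ranger
Suggests:
    caret,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
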