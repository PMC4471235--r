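Package: mdmnet
Title: Multiple Differential Modules Across Weighted Differential
    Co-Expression Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers gene modules that are simultaneously coherent in
    several weighted differential co-expression networks, one network per
    disease condition versus a common baseline.  Networks connect gene pairs
    whose first-order partial Pearson correlation clears a threshold and
    weight edges by the differential-expression significance of their
    endpoints.  Modules are grown from propagation-ranked seeds by greedy
    minimisation of a graph-entropy objective, assessed against
    degree-preserving permutation nulls with Benjamini-Hochberg control,
    and scored for connectivity rewiring between conditions with a
    spectral-norm dynamics statistic.  Includes module-level summaries
    (activity, regulation calls, phenotype correlation, gene-set
    enrichment), a planted-truth synthetic data generator for benchmarking,
    and a command-line interface over the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
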