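Package: pharmacoepimap
Title: Pharmacoepigenomic Biomarker Discovery from Drug Screens and DNA
    Methylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discovery pipeline for epigenetic biomarkers of drug response
    in cancer cell line screens. Fits per-CpG linear models of drug
    sensitivity (area under the dose-response curve) on methylation
    beta-values with covariate and principal-component correction, calls
    drug differentially methylated regions (dDMRs) by combining spatially
    correlated p-values (Stouffer-Liptak-Kechris with an estimated
    autocorrelation function and Sidak adjustment), links regions to
    proximal gene expression with Mann-Whitney rank tests under a
    permutation empirical null, replicates methylation-expression links in
    an independent tumour cohort (tgdDMRs), connects biomarker genes to
    drug targets on a directed signalling network with Yen's K-shortest
    loopless paths, and provides the accompanying enrichment and
    association statistics. Includes a synthetic-cohort generator so every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
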