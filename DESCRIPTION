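Package: purityforest
Title: Reference-Free Tumor Purity Estimation from Methylation Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the tumor-cell fraction of bulk tumor samples directly
    from Illumina 450K-style DNA methylation beta values, without matched
    normal tissue. CpG probes whose beta values are multimodal across a
    cohort (a signature of tumor-stroma admixture) are screened with
    Hartigan's dip statistic, and a two-step random-forest regression with
    out-of-bag model selection maps the retained probes to purity labels
    from a gold standard such as ABSOLUTE or ESTIMATE. Includes the LUMP
    immune-hypomethylation score, evaluation and per-entity quantile
    machinery, probe-annotation profiling against CpG islands, gene bodies,
    promoters and tumor-suppressor genes, and a synthetic tumor-stroma
    admixture simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    ranger,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
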