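Package: gutmix
Title: Reverse Weighted Quantile Sum Analysis of Prenatal Metal Exposure
    and the Gut Microbiome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline relating prenatal lead exposure to
    childhood gut-microbiome composition and function. Implements
    preprocessing of metagenomic taxa profiles (relative abundance,
    two-batch prevalence filtering, decile scoring with zeros pinned at
    zero), alpha/beta diversity testing (Shannon, Bray-Curtis,
    Kruskal-Wallis, adjusted linear regression, PERMANOVA with
    Freedman-Lane residual permutation), reverse-oriented weighted
    quantile sum regression with random subsets and repeated holdouts,
    taxa-wide association models with an eigenvalue-based effective
    number of tests, pathway overlap analysis of important taxa, and a
    zero-inflated Dirichlet-multinomial cohort simulator providing
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    nnet,
    stats,
    tools,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
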