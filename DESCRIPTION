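Package: cas10census
Title: Census of Type III CRISPR-Cas Loci, Cas10 Domains and Ancillary Effectors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully reproducible pipeline for censusing type III
    CRISPR-Cas loci. From per-genome protein sequences and a locus annotation
    table it identifies Cas10 proteins with position-specific scoring profiles
    calibrated to empirical Gumbel E-values, calls cyclase (GGDD-variant) and
    HD nuclease domains with two-stage profile-plus-literal-motif rules,
    dereplicates Cas10s by greedy identity clustering, types the ten known
    cyclic-oligoadenylate and SAM-AMP activated ancillary effector families in
    locus neighbourhoods, discovers novel effector candidates in effector-less
    cyclase-positive loci, and summarises the census with co-occurrence
    statistics and a binomial generalized linear model for inter-locus
    signalling. A synthetic-genome generator with planted ground truth makes
    every stage testable without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    jsonlite,
    yaml,
    ggplot2,
    generics,
    withr,
    Rcpp,
    ape,
    phangorn,
    Biostrings,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
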