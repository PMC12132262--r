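Package: indelrates
Title: Alignment-Free Estimation of Substitution and Indel Rates from k-mer Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the three fundamental parameters of an indel mutation
    channel - the substitution rate, the deletion rate, and the mean insertion
    length - from k-mer and k-span statistics of a pair of related DNA
    sequences, without computing an alignment of the full sequences. Provides
    the generative mutation channel with complete ground-truth bookkeeping,
    closed-form moment estimators with their expected-value machinery and
    concentration-bound calculator, a unitig-and-alignment observer that
    recovers the unobservable k-span counts from raw sequences, and a
    simulation harness for parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    withr,
    stats,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
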