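Package: mugakit
Title: Design, Quality Control and Analysis Tools for Mouse Universal
    Genotyping Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for Illumina Infinium-style mouse genotyping arrays
    built around the Collaborative Cross and Diversity Outbred founder
    strains. Implements information-maximizing marker selection over
    founder haplotypes (window scoring and beam search), array-level
    quality control (total-intensity statistics, Kolmogorov-Smirnov
    flagging, call-rate and sex-concordance checks, probe quality tiers),
    polar intensity normalization to log-R-ratio and B-allele frequency,
    trio-informed multiallelic cluster detection, Gaussian-mixture
    presence calling for engineered constructs, strain and subspecies
    informativeness analytics, congenic-background reconstruction with a
    hidden Markov model, copy-number screening helpers, and a synthetic
    data generator that emulates all of the above with full ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    ape,
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
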