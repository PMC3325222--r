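Package: founderage
Title: Dating Founder Mutations from Linkage-Disequilibrium Decay
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating the age of founder mutations from the
    decay of linkage disequilibrium around a disease locus. Implements
    conserved ancestral-haplotype detection among disease chromosomes,
    deterministic trio phasing, moment estimators of the time to the most
    recent common ancestor (proportion-of-ancestral-haplotypes and
    excess-allele-sharing inversions of (1 - theta)^g), a coalescent
    correction for exponential population growth, a composite-likelihood
    age estimator, Hardy-Weinberg and census-based demographic
    calculators, and a forward simulator of founder events (star or
    growth-coalescent intra-allelic genealogies) so every stage can be
    validated against known truth.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
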