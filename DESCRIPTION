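Package: asbind
Title: Allele-Specific RNA-Binding Protein Binding from eCLIP Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects allele-specific binding (ASB) of RNA-binding proteins at
    heterozygous single-nucleotide variants in eCLIP-Seq data. Allelic read
    counts are corrected for the crosslinking-induced sequence propensity
    estimated from the size-matched input control, replicate variance is
    moderated by a LOESS trend of the squared coefficient of variation against
    log2 mean coverage, and allelic imbalance is tested with an empirical
    Gaussian posterior followed by Benjamini-Hochberg adjustment. Includes a
    zero-truncated negative-binomial simulator of allelic counts, chi-square
    and Fisher comparators, precision-recall benchmarking, and the stepwise
    posterior quality filters used on real data.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    Biostrings,
    Rsamtools,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
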