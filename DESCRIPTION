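Package: xciscan
Title: X-Chromosome Inactivation Status from Allelic Imbalance at Expressed SNPs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers X-chromosome inactivation (XCI) status for X-linked genes
    from allelic imbalance (AI) measured at heterozygous expressed SNPs in
    female samples. Estimates the degree of XCI skewing per female from a
    subject-gene training set, classifies females by skewing strength (groups
    1, 2 and R), converts AI into expression from the inactive X as a fraction
    of the active X (%Xi) with skew-adjusted status boundaries, aggregates
    per-female calls into genic statuses (subject, variable escape, escape)
    with variable-escape subtypes, and runs downstream analyses: probe quality
    control (intensity-decay Tau thresholds, genomic-DNA ratio filters,
    two-probe concordance), positional adjacency clustering chi-square,
    cross-sample-set comparison, a mono-allelic screen in random-XCI females
    with Grubbs outlier exclusion, and allelic imbalance of histone ChIP
    signal across expression classes. Includes a synthetic cohort generator
    with ground truth so every stage is testable without array data.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
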