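Package: embryoscreen
Title: Trio-Based Whole-Genome Embryo Variant Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Inheritance-mode variant screening for preimplantation genetic
    testing (PGT) trios sequenced by whole-genome sequencing. Implements six
    parallel filter workflows (dominant heterozygous, recessive homozygous,
    compound heterozygous, X-linked, de novo, and a high-sensitivity failsafe),
    ClinVar and stacked-predictor pathogenicity grading, amplification-aware
    de novo false-positive gates (variant allele fraction and quality-by-depth),
    loss-of-heterozygosity segment detection with flanking-SNP rescue of
    expected-but-missing variants, binned trio read-depth copy-number calling
    with dosage-sensitivity annotation, tandem-repeat transmission concordance,
    and a synthetic trio generator emulating multiple displacement
    amplification artifacts with a complete ground-truth ledger.
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
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
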