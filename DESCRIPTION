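Package: gasel
Title: Genomic Assisted Selection for Line Breeding Programs
Version: 0.1.0
Authors@R:
    person("Gasel", "Developers", email = "gasel@example.org", role = c("aut", "cre"))
Description: Toolkit for merging genomic and phenotypic selection in autogamous
    line breeding programs. Implements kinship-enhanced analysis of unreplicated
    preliminary yield trials (KBLUP), RR-BLUP and GBLUP genomic prediction with
    REML variance components via a single spectral decomposition, check-based
    spatial adjustment of field trials, Piepho-Moehring and Cullis heritability
    estimation, a heritability-weighted selection index with sign-change marker
    pre-selection, two-tailed training population design, year-fold and
    leave-one-year-out cross-validation schemes, and a multi-year breeding
    program simulator for end-to-end evaluation without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    VariantAnnotation
Config/testthat/edition: 3
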