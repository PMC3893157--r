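Package: crconfound
Title: Cryptic Relatedness and Its Confounding Effect on Exposure Regressions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how undetected close kinship (cryptic relatedness) among
    cohort participants confounds ordinary regressions of a quantitative trait,
    such as systolic blood pressure, on environmental exposures. Implements
    method-of-moments identity-by-descent estimation (Z0/Z1/Z2, PI_HAT) from
    genome-wide SNP genotypes, relatedness calling and sample pruning,
    liability-threshold (Falconer-type) heritability estimation under mixed
    degrees of relatedness, paired exposure regressions on samples with and
    without cryptic relatives, and Chow-type tests of the parallel-regressions
    hypothesis. A synthetic-cohort generator with planted relative pairs, a
    polygenic liability and configurable subpopulation prevalences supports
    calibration and power studies, including plain-text PED/MAP genotype input
    and output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
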