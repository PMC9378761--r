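Package: eafg
Title: Early-Age Facial Growth Pattern Phenotyping and Genetic Association
Version: 0.1.0
Authors@R: person("EAFG", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify early-age facial growth from longitudinal
    2D facial photographs and to test its genetic basis. Facial landmark
    coordinates are converted into interocular-normalized distance
    phenotypes (10 horizontal, 11 vertical), per-person growth
    trajectories on relative age are fitted with quadratic curves and
    classified into five ordinal growth patterns (continued decrease,
    decrease-to-increase, constant, increase-to-decrease, continued
    increase), and the pattern codes are tested for single-SNP
    association with Wald and likelihood-ratio tests after call-rate,
    minor-allele-frequency and exact Hardy-Weinberg quality control.
    Includes a synthetic-cohort generator with planted genetic effects
    for end-to-end validation, measurement-level tail trimming,
    Bonferroni adjustment with significance tiers, locus clustering,
    two-cohort replication selection and modal-pattern concordance
    reports, plus a deterministic pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
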