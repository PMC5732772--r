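Package: uratemr
Title: Mendelian Randomization of Serum Urate Effects Using a Weighted
    Genetic Risk Score
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Individual-level Mendelian randomization built around a weighted
    uric-acid-transporter genetic risk score used as an instrumental variable
    for serum urate. Provides readers and validators for genotype dosage,
    phenotype and SNP-weight tables (TSV or biallelic VCF), weighted and
    allele-count risk score construction, ordinary least squares and
    two-stage least squares estimation with first-stage instrument-strength
    diagnostics, Durbin-Wu-Hausman endogeneity tests (contrast and augmented
    regression forms), subgroup-stratified analysis pipelines, and a
    calibrated cohort simulator with unmeasured confounding for validating
    every stage without access to individual-level study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite
Config/testthat/edition: 3
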