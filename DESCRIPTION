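Package: impuconcord
Title: Concordance-Based Evaluation of Genotype Imputation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to evaluate genotype imputation output against an
    independent genotyping array. Converts imputed posterior genotype
    probabilities to hard calls at a configurable calling threshold,
    applies iterative pre-imputation array quality control (missingness,
    minor allele frequency, heterozygosity, sex concordance), classifies
    each overlapping variant into the complete / flip (strand-swapped) /
    half / no-match allele-concordance taxonomy with explicit handling of
    ambiguous palindromic (A/T, G/C) sites, and summarises imputation
    quality scores (INFO / r-squared) stratified by minor allele
    frequency and by match class, on autosomes and the X chromosome
    separately. A Balding-Nichols admixture simulator generates synthetic
    multi-way admixed cohorts, split across two partially overlapping
    arrays, with pseudo-imputed probabilities carrying known discordance,
    strand-flip, monomorphic-collapse and no-call rates, so that the full
    evaluation pipeline can be exercised and calibrated without access to
    restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
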