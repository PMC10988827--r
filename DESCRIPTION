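Package: latcohort
Title: Phenotype Clustering and Rare-Variant Analysis for Laterality
    Congenital Heart Disease Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cohort studies of laterality congenital heart
    disease. Implements ontology-based quantitative phenotypic similarity
    (information-content based Lin scores over a phenotype ontology),
    gap-statistic cluster-number selection and Ward hierarchical
    clustering of proband phenotypes; rare-variant prioritisation with
    population-frequency and CADD thresholds, inheritance labelling and
    compound-heterozygote trans-phasing from clone reads; allele-based
    case-control enrichment statistics (odds ratios with Wald intervals,
    Fisher exact tests, expected-carrier computations); read-depth
    (RPKM) deletion screening, breakpoint-junction microhomology
    resolution and classification of Alu-Alu mediated rearrangements;
    and seeded synthetic-data generators with ground-truth bundles so
    every stage is testable without access to patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
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
    utils,
    vcfR
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
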