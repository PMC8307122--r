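Package: alltriage
Title: Variant Triage, Tier Classification and Ancestry Inference for Small Leukemia Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-exome variant triage for small acute lymphoblastic
    leukemia (ALL) cohorts sequenced without matched normal tissue. Reads
    annotated VCFs, restricts to coding consequences, subtracts variants seen
    in healthy controls, removes alleles common in a matched reference
    population, classifies the survivors by clinical-evidence level (OncoKB
    style, levels 1-4) and mutational-significance tier (Cancer Mutation
    Census style three-factor rules plus a Tier X rank for uncatalogued
    changes at tiered amino-acid positions), maps genes to targetable
    pathways, builds patient-by-variant carrier matrices with position-level
    aggregation (e.g. KRAS G12X) and stratified carrier frequencies, and
    infers genetic ancestry by classical multidimensional scaling of
    identity-by-state distances against a labelled reference panel. Includes
    a deterministic synthetic-data generator for cohort VCFs, catalogue
    snapshots and reference genotype panels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
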