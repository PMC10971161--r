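Package: nbscreen
Title: Variant Filtering and Interpretation for NGS-Based Newborn Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for the variant filtering and interpretation
    strategy used in next-generation-sequencing based newborn screening for
    inherited metabolic disorders. Implements a strict (likely) pathogenic
    variant filter (knowledge-base lookup, novel-truncating rule with a
    nonsense-mediated-decay exception, splice-region window, allele-frequency
    gate), a conditional VUS-extension filter keyed on a single heterozygous
    (likely) pathogenic variant in a recessive gene, mode-of-inheritance aware
    screening calls with compound-heterozygote, hemizygous and copy-number
    allele logic, carriership detection, a staged background-cohort assessment
    funnel, confusion-matrix outcome scoring against diagnostic truth, and a
    synthetic cohort generator for end-to-end testing without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
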