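Package: germscreen
Title: Germline Cancer Predisposition Screening in Patient Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for screening germline cancer
    predisposition variants in patient cohorts: multistep filtering of
    cohort variant calls (quality, candidate gene panel, population
    rarity, protein impact) with a per-step audit trail, a rule-based
    ACMG/AMP evidence-combination engine producing five-tier variant
    classifications with a rule trace, carrier-burden association of
    cohort pathogenic/likely-pathogenic carriage against population
    reference allele-count tables (odds ratios with Woolf confidence
    intervals and Fisher exact p-values), cohort-level carrier summaries
    by inheritance mode with recurrence screening and pedigree
    co-segregation counts, and a synthetic cohort simulator with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
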