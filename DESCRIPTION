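Package: germtriage
Title: Germline Variant Triage and Carrier-Burden Analysis for DNA-Repair Gene Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tiered pathogenicity triage of rare germline variants from a
    targeted gene panel (homology-directed repair and mismatch-repair genes),
    together with patient-level carrier aggregation and exact association
    statistics. Implements a rule-based classifier (allele-frequency filter,
    ClinVar assertion precedence, truncating/last-exon rule, splice-score rule,
    and an ESM1b/AlphaMissense concordance rule for missense variants),
    transcript consequence projection for SNVs and small indels, Fisher exact
    tests for 2x2 and 2xK tables by full enumeration (Freeman-Halton), odds
    ratios with Woolf confidence intervals, and a seeded synthetic-cohort
    simulator with planted effect sizes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
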