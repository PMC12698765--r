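Package: repairchoice
Title: CRISPR Editing Outcomes, Repair-Pathway Classification and Drug-Screen Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies CRISPR amplicon sequencing reads into DNA double-strand-break
    repair outcomes (unmodified, HDR, NHEJ, MMEJ, mix) using global alignment,
    canonical left-aligned lesion extraction and deletion-junction microhomology,
    and analyses multi-condition drug-repurposing screens built on those outcomes:
    mock-normalized fold-change metrics, sequencing-depth filtering, quartile-rule
    hit categories, detection-limit normalization of MMEJ, top-hit selection,
    target-class enrichment, principal component analysis, resazurin viability
    conversion, four-parameter logistic dose-response fits with EC75 reporting,
    and genotype survival contrasts for synthetic-lethality calls. A seeded
    synthetic-data generator emulates amplicon reads with known pathway labels
    and whole screens with planted drug effects so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
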