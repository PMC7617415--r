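Package: rasco
Title: Co-Occurrence and Clonality of Atypical BRAF and Ras Pathway
    Mutations in Colorectal Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classification of somatic BRAF mutations into kinase-activity
    classes 1, 2 and 3 and positional domains A, B and C, together with
    typical/atypical annotation of KRAS, NRAS and NF1 driver mutations;
    exact co-occurrence statistics over annotated tumor cohorts;
    purity- and copy-number-aware clonality inference relating variant
    allele frequency to mutant allele copy number; normalized 96-channel
    trinucleotide mutation spectra with causal-channel statistics and a
    logistic model of driver presence on channel activity; and a seeded
    synthetic cohort generator emulating a combined multi-study colorectal
    cancer dataset, so that every stage of the analysis is testable
    without access to controlled patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    vcfR
Config/testthat/edition: 3
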