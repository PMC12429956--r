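Package: netdrugmap
Title: Mapping Disease Genes and Drug Targets onto Pathway and Network Gene Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the co-localization of disease genes and drug
    targets on two gene-set universes: large mosaic pathway maps and the small
    functionally meaningful pathway segments ("networks") that compose them.
    The package computes per-element overlap scores and coverage counts for
    both universes, ranks networks by disease-gene content and by the number
    of drugs targeting them within disease groups, identifies disease-related
    networks (networks holding both a disease's genes and its drugs' targets),
    classifies drugs by the genetic support of their targets, and compares the
    proportion of genetically supported drugs across drug-development phases
    (all drugs, drugs in clinical trials, approved drugs) with a chi-square
    test and a balanced three-way ANOVA with Tukey HSD post-hoc tests. A
    seeded synthetic-data generator produces annotation universes with known
    group structure and a configurable approval-odds enrichment, so every
    stage of the pipeline can be exercised and validated without access to
    licensed annotation snapshots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
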