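Package: lipmine
Title: Genome Mining of Versatile Sterol Esterase and Lipase Candidates
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for discovering candidate versatile sterol
    esterases and lipases (alpha/beta-hydrolases of the Candida rugosa-like
    family) in protein FASTA proteomes. Stages: keyword harvest and
    GESAG/GGGF conserved-motif screening, neighbor-joining family placement
    against a labelled reference panel, transfer of Lip3-anchored sequence
    features (catalytic triad, oxyanion hole, lid-delimiting cysteine pair,
    N-glycosylation sequons) with lid hydrophobicity scoring, grid-based
    detection of intramolecular tunnels from the catalytic serine with
    4 Angstrom lining hydrophobicity and straightness classification, and a
    final substrate-preference ranking report. Includes synthetic proteome,
    reference-panel and toy-structure generators with known ground truth so
    every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
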