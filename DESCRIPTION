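Package: homeorep
Title: Homeodomain Repertoire Classification and Paralog Retention Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing homeodomain repertoires of early-branching
    metazoans from 60-column homeodomain alignments: rule-based class and
    subclass annotation from diagnostic residue signatures, secondary domains,
    loop insertions and intron positions; protein distance and neighbor-joining
    tree construction; midpoint rooting with root-to-tip branch-length
    statistics; species-specific paralog clade counting; genomic linkage
    scanning of co-located homeoboxes; and a birth-death repertoire simulator
    that provides ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
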