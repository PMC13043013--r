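Package: cyanophot
Title: Phototrophy Annotation of Cyanosphere Metagenome-Assembled Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
        role = c("aut", "cre"))
Description: Detects and classifies the two modes of anoxygenic bacterial
        phototrophy in metagenome-assembled genomes (MAGs) recovered from
        non-axenic cyanobacterial cultures. Screens MAG contigs against
        reference protein panels by six-frame translated homology search,
        builds photosynthesis gene cluster (PGC) inventories with
        reference-numbered synteny comparison, classifies microbial
        rhodopsins by nearest-reference subtree, diagnostic residues
        (D-85/T-89/E-96, G-156, K-292) and brp/blh operon context into bona
        fide light-driven proton pumps, calls dual phototrophy, and computes
        host-calibrated relative abundance and commonality metrics. Includes
        a synthetic MAG-collection generator with planted ground truth for
        end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
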