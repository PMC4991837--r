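Package: wrkyscan
Title: Annotation and Classification of WRKY Transcription Factor Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for genome-wide surveys of the WRKY
    transcription factor family. Detects WRKY domains (heptamer plus
    C2H2/C2HC zinc finger) in protein sequences, classifies genes into the
    standard groups and subgroups (Ia, Ib, IIa-IIe, III, IV) from zinc-finger
    spacer and signature motifs, types introns within domain-coding regions
    (phase and PR/VQR class), scans promoters for stress-response cis-elements
    and derives hormone-responsiveness categories, scans proteins for MAPK
    phosphorylation sites and docking motifs, detects tandem-duplication gene
    clusters on chromosomes, summarizes RPKM expression matrices, and builds
    bootstrapped neighbour-joining trees of domain alignments. A synthetic-data
    generator plants machine-readable ground truth (group labels, intron types,
    clusters, cis-elements, peak tissues) so every stage can be validated
    end-to-end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stringr,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
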