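Package: tkitdesign
Title: Two-Guide CRISPR Knock-In (TKIT) Design, Simulation and Quantification
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design automation and in-silico validation for two-guide,
    homology-independent CRISPR/Cas9 knock-in ("TKIT"-style) experiments in
    post-mitotic cells. Enumerates and pairs SpCas9 guides in non-coding DNA
    (5'UTR/introns) at a safe distance from splice junctions, builds the
    switch-and-flip donor whose reverse-orientation insertions regenerate
    intact Cas9 target sites, generates cloning primers for four-fragment
    guide-vector assembly and three-fragment HiFi donor assembly, simulates
    all edit outcomes (forward knock-in, re-cuttable reverse insertion,
    knock-out religation, junction INDELs) with splice-aware transcript and
    protein prediction, and implements the downstream quantification used in
    such studies: knock-in efficiency, KI/WT/KO cell classification,
    colocalization slope, and FRAP one-phase-decay fitting. Includes
    deterministic synthetic-data generators so the whole pipeline is testable
    without any genome download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    rtracklayer,
    GenomicRanges,
    minpack.lm,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: CRISPR, SequenceMatching, Alignment, Software
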