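Package: scrca
Title: Design and Simulation of Repetitive-Sequence Gene Synthesis by
    Seamless Cloning of Rolling-Circle Amplicons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: In-silico companion to the SCRCA gene-synthesis workflow for
    repetitive protein-polymer genes (elastin-like and resilin-like
    polypeptides and their block copolymers). Designs circular ssDNA ring
    templates, junction-spanning split oligos and rolling-circle
    amplification primers carrying seamless-cloning overlap extensions;
    predicts the theoretical amplicon ladder and stochastically simulates
    the amplicon pool, including incomplete-end intermediates that anneal
    into block-copolymer genes; performs in-silico overlap-directed
    assembly with open-reading-frame and affinity-tag verification;
    enumerates degenerate-codon (mixed-base) repeat-unit libraries and
    computes their diversity statistics; analyses sequencing reads of
    repeat libraries via terminal-unit extraction and counting; and ranks
    library mutants for directed evolution by pH-dependent net-charge
    shift and Kyte-Doolittle hydropathy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
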