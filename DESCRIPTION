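Package: rnamodkit
Title: Detection and Characterization of rRNA Base Modifications from
    Sequencing and Mass-Spectrometry Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools around the misincorporation signature that base
    modifications such as 1-methyladenosine (m1A) leave in RNA-seq data, with
    the mitochondrial 16S rRNA m1A947 site as the motivating use case.
    Includes modification-aware in-silico ribonuclease digestion with
    monoisotopic mass, negative-mode m/z and CID product-ion calculation;
    strand-aware RNA-DNA-difference (RDD) calling from aligned reads with
    coverage and per-strand fraction filters and read-edge artifact tests;
    orthologous-position anchoring across mitochondrial genomes;
    in-silico MAGE oligo design, overlap assembly, T7 run-off transcription
    and restriction-fragment (RFLP) prediction; reporter-kinetics summaries
    for growth experiments; and a seed-deterministic synthetic-data generator
    that emits aligned SAM reads, references and kinetics tables with
    machine-readable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
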