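Package: acrobar
Title: DNA-Barcode Species Identification for Acropora Corals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Species identification of Acropora corals from DNA barcodes.
    Implements a BLAST-style identification pipeline for the two loci most
    used in Acropora barcoding, the mitochondrial putative control region
    (mtCR) and the nuclear PaxC intron: curation of species-labelled
    reference databases, local alignment with Karlin-Altschul bit scores, a
    hierarchical assignment decision tree with percent-identity and
    bit-score tie-breaking, two-locus concordance, leave-one-out
    self-identification evaluation of reference databases, and a seeded
    simulator of two-locus barcode datasets with controllable intra- and
    inter-species divergence and cross-species haplotype sharing -- the
    regime in which barcode-based identification breaks down.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
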