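Package: predsip
Title: Detection of Isotopically Labeled Predatory Bacteria from rRNA-SIP
    Gradient Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for rRNA stable-isotope-probing (SIP) analysis of
    predator-prey interactions in microbial communities. Computes per-taxon
    enrichment factors from paired 13C/12C isopycnic gradient fractions,
    applies heavy-fraction abundance filters and labeling thresholds,
    classifies 16S rRNA gene sequences as potential predators by percent
    identity to verified predatory isolates, and screens taxon abundances
    against process-performance variables with Spearman correlation and
    Benjamini-Hochberg false-discovery control. A forward simulator of
    buoyant-density gradients, 16S sequence sets and sample metadata with
    known ground truth supports end-to-end testing without external data.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
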