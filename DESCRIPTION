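Package: chromdom
Title: Compositional and Structural Analysis of Purified Chromatin Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of native chromatin domains affinity-purified
    from budding yeast. Implements comparative iTRAQ reporter-ion enrichment
    calling with housekeeping/ribosomal background correction and tiered
    thresholds, propionylation-aware relative quantification of histone
    post-translational modifications from centroided MALDI peak lists,
    single-molecule psoralen-crosslinking electron-microscopy nucleosome
    footprint analysis (contour calibration, linearization, bubble-size
    binning and molecule classification), and purification-recovery
    accounting (recovery percentages, fold-excess over a reference locus,
    recombination efficiency, restriction-accessibility normalization and
    ChIP percent-of-input). Ships seeded synthetic-data generators with
    ground truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    optparse,
    withr
Config/testthat/edition: 3
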