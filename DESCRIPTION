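Package: plastidReporter
Title: Codon Optimization Diagnostics and Fluorescence Quantification for
    Plastid Reporter Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing and evaluating codon-optimized reporter
    genes for AT-rich chloroplast genomes, and for quantifying their
    expression. Builds codon-usage tables from plastome GenBank records,
    computes per-gene diagnostics (GC3, optimal and rare codon
    composition, synonymous-change accounting, mean codon frequency
    difference), recodes coding sequences toward a target usage table,
    quantifies chloroplast-localized fluorescence from two-channel
    confocal images (rolling-ball background subtraction, thresholding,
    watershed particle segmentation, per-particle channel ratios), and
    fits densitometric standard curves for in-gel protein
    quantification. Seeded synthetic-data generators provide a
    ground-truthed test surface for every component.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    EBImage,
    tiff,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Software, SequenceAnalysis, CellBiology
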