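Package: panelforge
Title: Design and Validation of High-Density SNP Genotyping Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of the marker-selection cascade used to
    build high-density SNP genotyping arrays for salmonid genomes: paralogous
    sequence variant (PSV) screening with doubled-haploid lines, multi-caller
    call-set intersection and INFO-field hard filtering, inter-marker spacing,
    probe flanking-sequence extraction, trimming and uniqueness checks,
    window-based density balancing and legacy-marker retention; plus
    post-genotyping validation (call rates, Axiom-style conversion categories,
    exact Hardy-Weinberg tests, MAF spectra), probe remapping to a second
    assembly, and binned linkage-disequilibrium decay after genomic-relatedness
    pruning. Includes a Wright-Fisher forward simulator so the whole pipeline
    is testable on synthetic populations with known structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
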