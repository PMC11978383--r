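Package: wgakit
Title: Manipulate Pairwise Whole-Genome Alignments in MAF, PAF and Chain Formats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pairwise whole-genome alignments: lossless
    interconversion among the MAF, PAF and UCSC Chain formats through a
    canonical coordinate model with exact CIGAR arithmetic; MAF indexing,
    region extraction with block slicing, and segmentation into bounded
    chunks; alignment statistics (gap-compressed identity, coverage,
    windowed gap divergence) and filtering; reference-projected pseudo-MAF
    matrices with per-base conservation scores; alignment-based variant
    calling to VCF with left-normalization of indels; dotplot export as
    segment tables and static SVG; and a deterministic simulator of genome
    pairs with planted variants and exact truth sets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
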