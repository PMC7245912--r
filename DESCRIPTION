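Package: plastocov
Title: Coverage Depth Visualization for Plastid Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality control of plastid genome (plastome) assemblies by
    visualizing read coverage depth in relation to the circular,
    quadripartite genome structure. Parses an annotated GenBank flatfile,
    derives the LSC/IRb/SSC/IRa partition from inverted-repeat
    annotations, computes windowed coverage depth from a sorted, indexed
    BAM file via a start/end event sweep, assesses equality of the two
    inverted repeats directly (sequence, length) and indirectly (gene
    complement and synteny), and renders a multi-layer circular map with
    low-coverage windows highlighted. Includes a synthetic fixture
    generator (annotated toy plastome plus a matching BAM with known
    ground-truth pileup) and a shell entry point for pipeline use.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    optparse,
    jsonlite,
    grDevices,
    graphics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
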