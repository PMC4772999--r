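Package: barcodeval
Title: Evaluation of DNA Barcode Reference Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to evaluate a species-labelled DNA barcode reference
    library (e.g. COI alignments): pairwise p-distances with pairwise
    deletion, intra- and inter-specific divergence summaries, global and
    local barcoding-gap statistics, distance-based specimen-identification
    criteria (best match, best close match, all species barcodes),
    tree-based identification criteria, single-linkage threshold clustering
    with taxonomic-accuracy scoring, single-threshold GMYC species
    delimitation on ultrametric trees, and a coalescent-style synthetic
    barcode generator with known truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    seqinr,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
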