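Package: vpav
Title: Pangenome Core and Auxiliary Gene Analysis for Vaccinium-Style Cultivar Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to classify genes of a cultivar panel as core (present in
    every accession) or auxiliary (absent in at least one) from orthogroup
    membership cross-checked against whole-genome-alignment synteny anchors,
    to model core/pan accumulation curves exactly by a hypergeometric closed
    form equivalent to averaging over every combination of accessions, to
    contrast structural and expression features of core versus auxiliary
    genes, to test term (GO) over-representation with FDR control, and to
    intersect positionally conserved core sets across species. Includes a
    ground-truthed synthetic pangenome generator so the full pipeline is
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
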