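Package: pathatlas
Title: Static Tiled Web Atlases from CellDesigner Pathway Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts CellDesigner molecular-interaction map files into
    self-contained, tiled, semantically zoomable static web atlases.
    Parses the CellDesigner SBML extension dialect into a typed map model,
    serializes species through the canonical naming grammar used for
    modification states, compartments and complexes, expands structured
    entity annotations with identifier hyperlinks (PMID, HUGO, UNIPROT and
    MIRIAM-registry tags), validates and tiles semantic-zoom view chains
    into 256-pixel tile pyramids, assembles browsable map bundles with a
    grouped selection panel, substring search and per-alias callouts, and
    maintains a versioned annotation-post store with archive semantics
    across map releases. A synthetic-fixture generator renders small maps
    and zoom views so the whole pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tools,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
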