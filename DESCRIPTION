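Package: hedkit
Title: Hierarchical Event Descriptor (HED) Annotation Engine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for annotating events in time-series recordings with
    third-generation Hierarchical Event Descriptors (HED). Loads and lints
    hierarchical vocabulary schemas in wiki and XML dialects, parses and
    validates HED annotation strings, converts between short and long tag
    forms under the unique-mapping rule, expands named definitions,
    assembles per-event annotations from BIDS-style events.tsv tables and
    JSON sidecars, resolves enduring events from Onset/Offset/Duration
    marks with Event-context propagation, extracts experiment timelines,
    and supports tag-based event search and epoch-window extraction. A
    bundled miniature base schema and synthetic experiment-design
    generators make the full pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
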