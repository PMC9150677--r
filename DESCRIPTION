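Package: neurometa
Title: Standardized Annotation Metadata for Connectomics Datasets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for storing, validating and querying annotation
    metadata attached to neuroanatomical entities (neurons, synapses,
    cortical layers) reconstructed from volumetric electron-microscopy
    datasets. Provides community-defined entity schemas with
    minimum-required-property validation and user-defined extensions, a
    document-oriented metadata store with eight retrieval endpoints,
    delimited-table import and JSON Lines round-tripping, a seven-template
    question catalog (119 parameterized questions) over synapse counts,
    layer widths, neuron lengths and excitatory/inhibitory balance, and a
    seeded synthetic connectome generator that emits exact ground-truth
    tallies for hermetic testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
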