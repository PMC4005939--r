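Package: ephystore
Title: Versioned Object Store and REST-Style API for Electrophysiology
    Data and Metadata
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A data-management platform for neurophysiological recordings.
    Combines a fixed object model for recorded electrophysiology data
    (blocks, segments, analog signals, spike trains, events, recording
    channels, sorted units) with hierarchical key-value metadata (sections,
    properties, values) in a single versioned object store. Numeric arrays
    are persisted as HDF5 datasets and can be retrieved partially by time
    window, with index bounds computed from object attributes and units.
    The store is exposed through a REST-style request interface with
    Django-style field-lookup query filters, relationship traversal,
    metadata-driven data selection, e-Tag conditional GET caching,
    per-object access control lists, and time-travel retrieval of any
    historical object version. A native client maps remote objects to R
    structures with lazy array fetching, and a seedable fixture generator
    produces a complete synthetic visual-stimulation experiment for testing
    and demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    R6,
    digest,
    jsonlite,
    rhdf5,
    stats,
    tibble,
    utils
Suggests:
    httpuv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
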