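Package: calmov
Title: Calcium Imaging Movie Analysis: Registration, Segmentation, DF/F
    Traces and Event Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A scriptable pipeline for single-plane calcium imaging
    recordings (e.g. nuclear-localized GCaMP in larval zebrafish): rigid
    motion correction by normalized cross-correlation template matching,
    nucleus segmentation (intensity projection, rolling-ball background
    subtraction, threshold plus marker-based watershed), per-pixel DF/F
    conversion against a user-defined baseline window, ROI trace extraction
    and Gaussian smoothing, sliding-window z-score peak detection with
    ternary (-1/0/1) output, stimulus-epoch response classification
    (OFF/ON/OFF-ON), ROI annotation and grouping, and two-file CSV export.
    Reads and writes multipage TIFF stacks and ImageJ .roi/.zip files, and
    ships a seeded synthetic-movie generator with ground truth so the whole
    pipeline can be exercised without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tiff,
    EBImage,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    optparse
Config/testthat/edition: 3
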