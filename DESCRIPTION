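Package: nucleval
Title: Evaluation, Simulation and Classical Segmentation of Nucleus Instance Masks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for object-level evaluation of nucleus instance
    segmentation in 2D microscopy: intersection-over-union (IoU) matching of
    predicted against target objects, thresholded precision/recall/F1, and the
    multi-threshold competition score used by the 2018 nucleus-segmentation
    data challenge. Includes lossless conversion between integer label masks,
    per-object binary mask directories and run-length-encoded submission CSVs;
    a seeded synthetic microscopy image generator emulating five visual image
    groups (small/large fluorescent, purple tissue, pink-and-purple tissue,
    grayscale tissue); a configuration-free classical reference segmenter
    (grayscale transform, thresholding/distance-transform/watershed,
    seeded-watershed refinement with nuclear size priors) with an automatic
    image-group classifier; and inter-observer agreement statistics
    (per-object IoU distributions, F1 at 0.7 IoU).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    tiff,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
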