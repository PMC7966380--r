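Package: tipr
Title: Transillumination Intestinal Projection Video Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for transillumination imaging of intestinal
    motility in freely moving mice: silhouette- and image-moment-based rigid
    frame registration, curved-centerline spatial-temporal (kymograph)
    mapping, spectral estimation of segmentation and peristalsis frequencies,
    behavior-aware stitching of long recordings, dual-wavelength channel
    demultiplexing, tube-phantom contrast and width metrics, and
    shift-and-add light-field refocusing with depth-index mapping. Includes a
    synthetic-scene generator with known ground truth (motor patterns, rigid
    poses, depths) so every stage can be validated without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
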