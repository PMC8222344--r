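Package: ctqc
Title: Slice-by-Slice CT Patient Centering, Image Noise and Dose Quality Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the consequences of vertical patient
    off-centering in computed tomography. Provides a ground-truthed synthetic
    anthropomorphic torso generator (with additional transfer mattresses,
    vertical offsets, topogram magnification and phenomenological tube-current
    modulation), portable CT series input/output with per-slice acquisition
    metadata, Otsu-threshold body contouring, Hounsfield-range tissue
    segmentation, boundary-aware local noise maps with a global noise level,
    per-slice barycentre off-centering metrics, modulated-mAs profile
    extraction, and paired reference-versus-test acquisition comparison with
    percent differences, Student's t-tests and CTDIvol deltas.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    data.table,
    jsonlite,
    stats,
    utils,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
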