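Package: braggsense
Title: Colorimetric Diffraction Analysis for Lipid Multilayer Grating Biosensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-analysis pipeline for label-free optical biosensing with
    aptamer-functionalized lipid multilayer diffraction gratings. Identifies
    Bragg-diffraction pixels in RGB time-lapse micrographs by green:red
    channel-ratio thresholding, refines them by one-standard-deviation
    selection within fluorescence (grating-height) bins, and extracts
    baseline-normalized sensorgrams and percent-change response maps.
    Includes a ground-truthed synthetic image generator embodying the
    transduction physics (fluorescence proportional to multilayer height,
    diffraction efficiency linear in height up to one tenth of the grating
    line width, pseudo-first-order binding response), so every stage of the
    pipeline is testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
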