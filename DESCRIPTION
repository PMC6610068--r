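Package: kymovel
Title: Unbiased Red Blood Cell Size and Velocity from Line-Scan Kymographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Scan-speed-aware measurement of red blood cell size and
    velocity from laser line-scan (space-time) images. Because a scanning
    microscope acquires the pixels of each line sequentially, the shadow an
    unlabeled cell leaves in a kymograph is stretched or compressed and its
    stripe slope biased, by up to 100 percent at high flow speeds. The
    package provides the closed-form correction equations and their
    inversions with explicit direction and singularity handling, a
    first-principles simulator of line-scan acquisition (per-pixel timing,
    bidirectional sweeps, noise) serving as an independent oracle, SVD- and
    Radon-based stripe-angle extraction with windowing and quality flags,
    vessel-diameter measurement, a Levenberg-Marquardt fit recovering the
    scan speed from paired bidirectional apparent velocities, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
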