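Package: cherenkovpol
Title: Polarization Imaging for Cherenkov-Based Radiotherapy Dosimetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to turn four-angle polarizer image stacks of Cherenkov
    light from an irradiated water tank into projected dose measurements.
    Per-pixel Malus-law decomposition separates polarized from unpolarized
    signal (DoLP/AoLP maps); a simplified condensed-history Monte Carlo of
    electron and photon transport in water supplies polar and azimuthal
    Cherenkov emission distributions; camera-geometry correction maps remove
    the emission anisotropy so that the corrected polarized image is
    proportional to the projected dose. Includes image preprocessing
    (temporal median, background subtraction, cos^4 flat-field), depth-dose
    and profile extraction with field-size and difference statistics, and a
    forward simulator that renders realistic synthetic polarizer stacks from
    a known ground truth so every stage is testable without camera data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
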