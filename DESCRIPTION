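Package: holoscan
Title: Wavelength-Scanning Pixel Super-Resolution Lensfree Colour Holography
Version: 0.1.0
Authors@R: person("holoscan", "maintainers", email = "holoscan@example.org",
    role = c("aut", "cre"))
Description: Reconstruction pipeline for wide-field lensfree in-line colour
    holographic microscopy.  Implements angular-spectrum free-space
    propagation, wavelength-scanning pixel super-resolution with
    Gerchberg-Saxton style multi-wavelength phase retrieval on the red, green
    and blue wavebands, and YUV-space chroma smoothing that removes
    rainbow-like colour artifacts while preserving luminance detail.  A
    physically faithful forward simulator (plane-wave illumination,
    pixel-aperture integration, optional shot noise) generates hologram
    stacks of resolution targets and stained-tissue-like phantoms so the
    whole pipeline is testable without experimental data.  Includes USAF1951
    three-bar contrast metrics and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    jsonlite,
    yaml,
    png,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
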