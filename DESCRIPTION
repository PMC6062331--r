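Package: framecodec
Title: Frequency-Multiplexed Single-Shot Videography: Encoding, Decoding and
    a Kerr-Gate Light-in-Flight Simulator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Encodes a sequence of 2D image frames into a single camera
    exposure by superimposing unique sinusoidal spatial carriers, and decodes
    them again by frequency-sensitive 2D spatial lock-in demodulation
    (band-pass isolation in reciprocal space, digital transfer to the origin,
    inverse Fourier transform). Includes reciprocal-space codebook planning
    with conjugate-aware carrier packing and dynamic-range accounting, a
    pump-probe optical Kerr-gate light-in-flight simulator that generates
    physically motivated ground-truth frame sequences, post-decode
    spatiotemporal interpolation and fidelity/crosstalk metrics, TIFF and
    YAML I/O, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    pracma,
    stats,
    tiff,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
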