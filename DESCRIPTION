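Package: photokin
Title: Density Shaping of Photokinetic Swimmers by Projected Light
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling and controlling the spatial density of
    light-responsive (photokinetic) swimming bacteria whose speed is set by
    a projected grayscale light pattern. Includes the hyperbolic
    speed-vs-intensity response with a two-timescale (instantaneous jump +
    exponential) speed memory, an agent-based simulator of smooth swimmers
    with per-agent speed memory in a 2-D light landscape, the memory-blur
    convolution model that predicts the stationary density from the inverse
    of the blurred speed map, differential dynamic microscopy (DDM) analysis
    of synthetic image stacks with a Schultz-distributed swimmer
    intermediate scattering function, a microscope-like renderer and the
    associated flat-field/percentile image-analysis chain, a closed-loop
    proportional feedback controller of the illumination pattern against a
    target density image, and closed-form estimates comparing active
    patterning with passive optical trapping of Brownian colloids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
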