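Package: canntrack
Title: Continuous Attractor Network Object Tracking with Fixed-Point and
    Many-Core Emulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Implements a complete software stack for fast object tracking
    with a two-dimensional continuous attractor neural network (CANN): the
    discretized bump dynamics with a distance-aware local connection field,
    frame-difference stimulus encoding of grayscale video, a synthetic scene
    generator and OTB-convention sequence I/O, fixed-point quantization of
    the recurrent loop via a constant-restricted scaling chain rule, a
    deterministic planner that slices the network onto fan-in/fan-out
    constrained functional cores, a behavioral simulator of the mapped
    many-core network that is bit-exact against the quantized reference
    pipeline, and standard tracking-accuracy metrics (center error, overlap,
    precision/success curves, AUC) with OPE/TRE/SRE evaluation protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
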