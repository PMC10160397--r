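Package: dflgmd
Title: Directionally Selective Fractional-Order LGMD Collision-Sensing
    Visual Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Implements a five-layer, fractional-order, directionally
    selective model of the insect lobula giant movement detector (LGMD)
    and direction-selective neurons.  Grayscale image sequences are passed
    through a photoreceptor layer with ON/OFF channel splitting, delayed
    Gaussian lateral inhibition, a summing layer, a correlation-type
    direction layer over eight canonical motion directions, and
    direction-selective LGMD units whose membrane dynamics follow a
    Grünwald-Letnikov discretisation of a fractional-order differential
    operator.  The package reports per-direction LGMD responses, a
    per-frame motion-direction estimate, and a collision-peak summary,
    and ships a synthetic stimulus generator (looming, receding and
    translating objects with optional Gaussian noise at a prescribed
    signal-to-noise ratio) so the network can be exercised end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
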