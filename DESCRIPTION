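Package: onoffdomains
Title: ON/OFF Domain Mapping and Receptive-Field Structure in Mouse V1
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to map ON/OFF domains in mouse primary visual cortex from
    sparse-noise imaging experiments and to test the biased-input account of
    their origin. The package estimates ON and OFF receptive-field kernels by
    event-triggered averaging, classifies cells as ON, OFF, simple or complex,
    builds kernel-density difference maps with label-shuffle Monte-Carlo level
    sets, aligns cortical and visual coordinates by canonical correlation
    analysis, and models simple-cell receptive fields as non-negative
    combinations of neighboring ON/OFF receptive fields. A synthetic-population
    simulator with a known ON/OFF bias field, affine retinotopy and LN-Poisson
    responses provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
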