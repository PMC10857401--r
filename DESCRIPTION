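Package: hdpress
Title: Hyperdimensional Computing for Pressure-Mat Activity Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Noise-resilient hyperdimensional computing (HDC) classifier for
    pressure-mat human activity recognition. Encodes 32x16 pressure frames and
    7-frame activity sequences into low-dimensional hypervectors via
    window-based local random-projection encoding with positional and temporal
    ID binding, trains nearest-prototype classifiers with mistake-driven
    retraining, and evaluates robustness under input, sensor, and
    memory/communication noise. Includes a seeded synthetic pressure-mat data
    generator for static postures and dynamic activities, a noise-sweep
    experiment harness, dataset/model persistence, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
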