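Package: axonmt
Title: Quantification of Axonal Microtubule Plus-End Dynamics and Bundle
    Disorganisation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify microtubule plus-end dynamics and bundle
    disorganisation in neurons from fluorescence microscopy. Implements
    end-binding (EB) protein comet measurement (length, mean intensity and
    their product, the comet "amount"), kymograph construction and
    trajectory extraction from time-lapse stacks, parameterised 2D
    plus-end particle tracking with gap closing, axon morphometrics
    including the microtubule disorganisation index (MDI), and a
    nonparametric statistics layer with parallel-control normalisation.
    A synthetic-data module renders axon stills and comet movies with
    known ground truth so every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    graphics,
    grDevices,
    jsonlite,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
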