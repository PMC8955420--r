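Package: asmapr
Title: Asymmetry-Map Feature Engineering for EEG Emotion Classification
Version: 0.1.0
Authors@R: person("asmapr", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Band-wise differential-entropy (DE) features from windowed
    multichannel EEG, a pairwise-channel asymmetry tensor (AsMap) rendered
    as an image-like CNN input, the classic DE/DASM/RASM/DCAU baseline
    feature vectors, a compact convolutional feature extractor with a dense
    softmax head, and a synthetic-EEG simulator with class-conditioned
    hemispheric band-power asymmetry used as the test bed. Includes EDF,
    CSV and HDF5 recording I/O, packaged 62-channel and 32-channel
    montages, and a command-line pipeline (simulate, extract, train,
    evaluate).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    optparse,
    rhdf5,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
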