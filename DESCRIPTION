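Package: probefit
Title: Biophysical Sequence-Recognition Models from Selection and Sequencing Data
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood inference of biophysically interpretable
    sequence-recognition models from multi-round selection-and-sequencing
    count data (SELEX and related assays). Fits position-specific binding
    free-energy matrices with optional pairwise letter couplings, multiple
    binding modes, dimer cooperativity and non-specific binding through a
    sliding-window partition function; supports cumulative, non-cumulative
    and kinetic selection models, joint multi-experiment likelihoods,
    extended alphabets for chemically modified letters, absolute dissociation
    constants from input/bound/free fraction sequencing, catalytic
    efficiencies from enzyme time-course display data, electrophoretic
    mobility shift binding-curve fits, model quality scores, and offline
    simulators for every supported assay family.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse,
    deSolve
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
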