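Package: cmaplin
Title: Linear Stimulus-Response Modelling of Multi-CMAP Recordings for
    Nerve-Function Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating peripheral nerve function from trains of
    compound muscle action potentials (CMAPs) evoked at graded stimulus
    intensities. Provides trigger-aligned epoch segmentation and grand
    averaging of evoked EMG, peak-to-peak amplitude extraction,
    baseline-based and baseline-free (per-trial) normalization of
    stimulus-response recruitment curves, ordinary least-squares fitting of
    the linear nerve model y = a*x + b, a linear support-vector-machine
    intervention criterion separating healthy from injured nerves, paired
    condition-wise statistics, and a synthetic cohort generator with an
    axon-population recruitment model and graded conduction-block injury.
    Includes readers and writers for delimited-text and EDF two-channel
    (EMG + trigger) recordings and quantification of nerve-incision extent
    from binarized images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    EBImage,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
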