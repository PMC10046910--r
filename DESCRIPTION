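Package: kcsfcnet
Title: Kernel Cross-Spectral Functional Connectivity Networks for
    Motor-Imagery EEG Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements KCS-FCnet, a shallow neural decoder for binary
    motor-imagery EEG whose core is a learnable Gaussian-kernel
    cross-spectral functional connectivity layer: temporal 1-D
    convolutions extract frequency patterns per channel, a Gaussian
    kernel turns each pair of filtered channels into a functional
    connectivity value, and a softmax readout over the vectorized
    connectivity matrix predicts the imagined movement. The package
    covers the full analysis pipeline around the model: synthetic EEG
    generation with planted band-limited channel coupling, Fourier
    resampling and Butterworth band-pass preprocessing, cross-validated
    scoring (accuracy, Cohen's kappa, AUC) with a grid search over the
    number of temporal filters, subject stratification by k-means on a
    bounded score matrix, two-sample Kolmogorov-Smirnov pruning of
    connections, quadratic Renyi entropy of pruned connectivity, and
    channel-relevance and edge-list exports for topographic displays.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    signal,
    pROC,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
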