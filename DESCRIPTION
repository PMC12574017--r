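Package: emgdecode
Title: Training-Speed Diversity for Continuous EMG Kinematic Decoders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and offline analysis of continuous myoelectric
    decoding across movement speeds. Generates synthetic 32-channel surface
    EMG driven by three-degree-of-freedom kinematics at slow, medium and fast
    trapezoidal speed profiles; extracts the 528-feature smoothed
    mean-absolute-value representation; trains Kalman-filter and
    convolutional-LSTM continuous decoders on single- and mixed-speed
    datasets; and quantifies cross-speed generalization with intended and
    unintended movement RMSE, dead-band (15 percent window) RMSE, log mean
    absolute jerk, permutation t-maps (SnPM) and the associated group
    statistics (Anderson-Darling screening, one-way ANOVA, Dunn-Sidak
    post-hoc tests).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    nortest,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
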