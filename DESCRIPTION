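Package: pacorrect
Title: Pulse-Artifact Removal for EEG Recorded in the MR Scanner
Version: 0.1.0
Authors@R: person("EEG", "Methods Lab", email = "eeg@example.org", role = c("aut", "cre"))
Description: Removes the ballistocardiogram (pulse) artifact from EEG
    recorded during simultaneous fMRI. Implements Optimal Basis Set (OBS)
    template subtraction followed by extended-infomax ICA, four criteria
    for marking cardiac-related independent components (variance
    contribution, hemispheric template correlation, partial
    autocorrelation, and a wavelet time-locking score), and three
    validation metric families (peak-to-peak ratios, autoregressive
    band-power ratios with a quality coefficient, and time-frequency
    mean-derivative measures). Ships a ground-truthed synthetic EEG-in-MR
    generator, BrainVision and EDF readers and writers, an end-to-end
    pipeline, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
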