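Package: statereach
Title: Internal-State Models of Trial-to-Trial Movement Variability with
    Intracranial Spectral Cluster Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Fits trial-by-trial internal-state (state-space) models of
    behavior in a center-out instructed-speed reaching task, where a
    decaying error state and perturbed state drive reaction time and
    speed error. Provides a synthetic task and local field potential
    (LFP) generator, Morlet-wavelet spectral preprocessing with
    per-frequency log-power normalization, hierarchical cluster-based
    permutation statistics relating internal states to time-frequency
    power across channels and subjects, and encoding- and
    connectivity-strength analyses with performance-based region
    selection.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
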