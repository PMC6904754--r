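Package: placentafbv
Title: Placental Fractional Blood Volume from Contrast-Enhanced MRI and CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for estimating placental
    fractional blood volume (FBV) in the pregnant mouse with blood-pool
    contrast agents. Provides a multi-compartment digital phantom of the
    pregnant abdomen, a spoiled gradient-recalled-echo (GRE) forward signal
    model, variable flip angle (VFA) T1 estimation by linear least squares,
    per-placenta FBV from relaxation-rate changes normalized to an inferior
    vena cava blood reference, the paired CT Hounsfield-unit enhancement-ratio
    estimator, and Bland-Altman / Wilcoxon rank-sum agreement statistics.
    Includes minimal NIfTI-1 volume I/O and JSON/YAML study manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
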