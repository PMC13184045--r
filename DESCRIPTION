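Package: suvshift
Title: Quantifying Contrast-Enhanced CT Attenuation-Correction Bias in PET SUV Measurements
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify the bias introduced in PET standardized uptake
    values (SUV) when a contrast-enhanced diagnostic CT (CE-CT), rather than the
    dedicated low-dose attenuation-correction CT (AC-CT), is used to build the
    511 keV attenuation map. Provides a seeded synthetic cohort and voxel
    phantom generator calibrated to published organ attenuation and uptake
    distributions, HU-to-mu conversion and per-organ attenuation extraction,
    spheroid and 41% isocontour volume-of-interest quantification, paired
    nonparametric cohort statistics (exact Wilcoxon signed-rank, robust
    summaries, correlations, densities), and a Deauville-score
    misclassification probability model based on the uncertainty of the
    SUV-ratio regression between the two reconstructions.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
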