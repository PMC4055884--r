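Package: tailflip
Title: Simulation and Robust Analysis of a Zebrafish Locomotor Nociception Assay
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a short-term behavioral nociception assay in zebrafish in
    which locomotor activity, measured as tail-flips per minute by an
    impedance biosensor or as swimming speed from video tracking, is compared
    before and after a noxious or analgesic treatment. Provides a
    ground-truthed generator of burst-structured tail-flip trains, biosensor
    traces and arena trajectories; an event detector (band-pass filtering,
    automatic gain control, adaptive sharpness thresholding, false-positive
    rejection); baseline normalization of each fish to its stable
    pre-treatment median; 20 percent Winsorized location summaries with
    standard errors; a rank-based nonparametric marginal model for the
    group-by-time repeated-measures design (relative treatment effects and
    ANOVA-type statistics with moment-matched degrees of freedom); and
    Monte-Carlo power and minimal-sample-size estimation for the full
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    rlang
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
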