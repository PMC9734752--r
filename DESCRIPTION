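Package: mirrorplayer
Title: Virtual Partner Dynamics and Synchrony Analysis for the Mirror Game
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a virtual mirror-game player whose two hands are driven
    by a pair of second-order Kuramoto phase oscillators with Perlin-noise
    radius modulation, runs closed-loop dyad trials against synthetic human
    partners in the human / no-coupling / coupling conditions, extracts
    instantaneous phase and synchrony measures (relative phase, Kuramoto order
    parameter, phase-lock intervals, time-in-sync from button streams), and
    reproduces the associated statistical pipeline (Shapiro-Wilk gating,
    Wilcoxon signed-rank and paired t tests, human-baseline correction,
    Cliff's delta effect sizes with categorical labels).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
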