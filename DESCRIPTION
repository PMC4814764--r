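Package: attune
Title: Anisotropic Cross-Recurrence Analysis of Coded Gesture and Speech Streams
Version: 0.1.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the dynamic attunement of two coded behavioral
    streams (prototypically gestures and speech scored on a 1-7 skill-level
    scale). Coded event tables are rasterized to 1 Hz categorical series,
    matched at the level of skill tiers (sensorimotor, representational,
    abstract), and analyzed with categorical cross-recurrence quantification:
    recurrence rate, anisotropic laminarity, trapping time and maximum line
    length computed separately for vertical and horizontal line structures,
    tier-restricted recurrence, and relative-difference asymmetry scores.
    A diagonal profile around the line of synchrony yields leader-follower
    measures (percentage of synchrony, RR_peak, tau_peak, Q_LOS). Inference
    uses Monte Carlo permutation tests with Cohen's d effect sizes and
    permutation-based correlations. A synthetic-cohort generator with known
    ground-truth lag, tier occupancy and dwell asymmetry makes the whole
    pipeline testable without observational data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
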