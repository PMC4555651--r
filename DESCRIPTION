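Package: ratfield
Title: Open-Field Trajectory Scoring and Drug-Synergy Statistics for
    Hemiparkinsonian Rats
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Scores open-field behaviour of unilaterally 6-OHDA-lesioned
    rats from three-point (nose, centre, tail) video-tracking exports:
    total distance travelled with a minimal-distance gate, ipsiversive and
    contraversive 360-degree turns from the unwrapped body-axis angle,
    time spent in a stretched (non-bent) posture, and space occupancy as
    the mean 10-second gyration radius.  Includes a state-machine
    simulator of the main locomotor phenotypes (vehicle-like, stereotyped
    circling, straight exploration) for fully synthetic cohorts, and the
    factorial statistical layer used to classify two-drug interactions as
    additive or synergistic: Levene's test, Box-Cox-guided square-root or
    log transformation, two-way ANOVA with the interaction term as the
    synergy criterion, Tukey post hoc comparisons among the eight cell
    means, and Student's t-tests for comparator groups.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    Rcpp,
    car,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE, load = "source")
RoxygenNote: 7.3.3
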