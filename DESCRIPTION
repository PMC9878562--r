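Package: migratrack
Title: Tracklet-Based Motility Analysis and Leader-Follower Chemotaxis
    Simulation for 3D Cell Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analyzes time-lapse single-cell migration tracks from 3D
    chemotaxis chambers: reads and regularizes tracking-software exports,
    decomposes tracks into fixed-length tracklets, computes instantaneous
    motility measures (displacement, path length, velocity, continuous
    arrest coefficient, directionality), classifies tracklets into four
    behavioral gates on the arrest-directionality plane, and quantifies
    contact-independent cell-to-cell influence via motile-neighbor velocity
    stratification and directionality lead-lag scoring. Includes an
    agent-based simulator of leader-follower lymphoma migration in which
    chemokine-scavenging leader cells chemotax along a CXCL12 gradient and
    emit a short-range LTB4 relay cue that, jointly with CXCL12, rescues
    migration of otherwise immobile follower cells.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
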