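Package: drivesim
Title: Stochastic Simulation of Homing Gene-Drive Population Suppression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-generation stochastic simulation of CRISPR homing gene
    drives designed to suppress insect populations. Implements a classic
    female-fertility single drive (ffSD) and two binary-expression double-drive
    designs, one sterilising carrier mothers (ffBED) and one spreading a seminal
    toxin through "terminator" males (sBED). The life cycle couples homing and
    resistance-allele formation during gametogenesis with intended and
    unintended fitness costs, polyandrous mating, a mate-finding Allee effect,
    Beverton-Holt density-dependent larval survival, and collapse detection.
    An experiment layer runs replicate releases, computes elimination rates,
    genetic load and allele-frequency trajectories, and sweeps drive and
    population parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
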