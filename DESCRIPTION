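Package: amplimotion
Title: Calibrated Motion Amplification and Exergame Simulation for Motor Rehabilitation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A hardware-free motion-processing toolkit for accessibility-oriented
    exergames. Weak limb movements captured as 20-joint skeleton streams are
    amplified per axis and per direction by factors obtained from a user
    calibration, retargeted onto a full-range avatar skeleton with analytic
    two-bone inverse kinematics, and fed into deterministic mini-game state
    machines (climbing, rowing, hitting, flying) driven by distance and speed
    gadgets. Includes a seeded synthetic-motion generator emulating impaired
    and unimpaired players, readers and writers for BVH and joint-stream files,
    and the two-sample statistical pipeline (Levene gate, pooled t, one-way
    ANOVA, Kruskal-Wallis) used to compare player cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), car
Config/testthat/edition: 3
RoxygenNote: 7.3.3
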