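Package: gridwave
Title: Spiking Continuous-Attractor Grid-Cell Network with Theta Sequences and Replay
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates a fully spiking continuous-attractor network of grid
    cells: five overlapping populations of leaky integrate-and-fire neurons on
    a two-dimensional neural sheet, with velocity-modulated excitatory drive,
    theta-oscillating inhibitory drive, and brief allocentric corrections.
    The network path-integrates animal trajectories, produces triangular-lattice
    activity bumps and grid cells, and -- depending on behavioural state --
    theta phase precession, theta sequences, or replay carried by traveling
    activity wavefronts. Includes the accompanying analysis pipeline:
    tetrode-style neuron selection, rate maps and firing fields, circular-linear
    phase statistics, Bayesian population decoding, theta-sequence averaging,
    replay detection, and attractor-bump size and speed characterization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    MASS,
    yaml,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
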