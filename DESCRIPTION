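Package: peristim
Title: Particle-Based Simulation of Peristalsis with a Reinforcement-Learning
    Controller
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discrete-multiphysics simulation of a contractile fluid-filled
    tube: a weakly compressible smoothed-particle-hydrodynamics fluid (Tait
    equation of state, pairwise artificial viscosity) coupled to a
    lattice-spring membrane with Hookean bonds, tether springs and radial
    contraction actuation, interacting through a repulsive interface
    potential and cross-phase viscous forces that approximate no-slip. The
    ten axial membrane sections are actuated by a deep Q-learning agent
    (10-50-50-10 value network, epsilon-greedy exploration) rewarded by the
    forward displacement of the fluid centre of mass, so that peristaltic
    coordination is learned rather than prescribed. Includes tube geometry
    presets, a physics-free surrogate task for agent testing, training and
    rollout loops, JSON checkpoints and extended-XYZ trajectory export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
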