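Package: embryomech
Title: Mechanical Simulation of Blastomere Arrangement in Nematode Eggshells
Version: 0.1.0
Authors@R: person("Embryomech", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Particle-based mechanical model of the early nematode embryo:
    up to four blastomeres, treated as soft spheres moving by overdamped
    Langevin dynamics inside a rigid ellipsoidal eggshell. Implements a
    repulsion-only (RO) and an asymmetric-attraction (AA) pairwise force law,
    programmed cell divisions (wild-type and perturbed orientation classes),
    a contact-graph classifier of four-cell arrangement patterns (pyramid,
    diamond, T-shaped, linear, T-reverse, H-shaped), and replicated
    aspect-ratio sweeps at constant eggshell volume.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
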