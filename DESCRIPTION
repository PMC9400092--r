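Package: skipper
Title: Bayesian Reconstruction of Potential Energy Landscapes from Noisy
    Particle Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers arbitrary-shape potential energy landscapes from noisy 1D
    and 2D particle trajectories governed by overdamped Langevin dynamics.
    Places a structured-kernel-interpolation Gaussian-process prior on the
    potential at a fixed grid of inducing points and samples the joint
    posterior over the latent trajectory, the potential, the friction
    coefficient, and the measurement-noise variance with a Gibbs sampler
    (Metropolis-Hastings within Gibbs for positions and friction, exact
    conjugate draws for the potential and the noise variance). Includes a
    forward-Euler Langevin simulator with Gaussian measurement noise for
    generating benchmark data, the classical Boltzmann histogram baseline,
    credible-band summaries, and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
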