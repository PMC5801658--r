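Package: stochimm
Title: Stochastic Within-Host Dynamics of Pathogen-Induced Autoimmunity
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and fluctuation analysis for a seven-compartment
    within-host model of immune response to viral infection and subsequent
    autoimmunity via molecular mimicry. Provides the deterministic ODE core
    with closed-form steady states and stability classification, the exact
    17-reaction continuous-time Markov chain with a Gillespie sampler, the
    Ito chemical-Langevin SDE with the block-structured 7x11 diffusion
    factor and an Euler-Maruyama integrator, and the linear-noise
    approximation with stationary fluctuation covariances obtained from the
    Lyapunov equation by a Bartels-Stewart solver. Experiment drivers
    reproduce bistable ensemble classification, bimodal stationary
    distributions fitted by a two-component Gaussian mixture, basin-of-
    attraction probability maps over initial conditions, and parameter-plane
    maps of fluctuation variance.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    Matrix,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
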