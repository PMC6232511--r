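Package: reverbkit
Title: Simulation and Subsampling-Invariant Estimation of Reverberating
    Neural Network Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying cortical population dynamics near a phase
    transition. Simulates driven branching-process activity parameterized by
    the neural efficacy m (population spike counts, neuron-resolved rasters,
    time-varying m schedules, subsampled observations), estimates m and the
    intrinsic network timescale from possibly subsampled activity by
    multistep regression (lag-dependent slopes fitted as b * m^k, which is
    invariant under spatial subsampling), and computes the analytic response
    properties attached to m: sensitivity 1/(1-m), stationary rate h/(1-m),
    amplification, intrinsic timescale -dt/log(m), a synaptic-fluctuation
    safety margin from criticality, and the task-optimal efficacy maximizing
    a goal function that trades desirable against detrimental diverging
    properties.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
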