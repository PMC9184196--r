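Package: fhnsync
Title: Master-Slave Synchronization of Coupled FitzHugh-Nagumo Neural Networks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and control of master-slave (drive-slave) pairs of
    gap-junction-coupled FitzHugh-Nagumo neural networks under external
    electrical stimulation, ionic disturbances, optional transmission delays
    and common additive Gaussian noise.  Implements adaptive membrane-input
    control laws for the non-delayed and delayed configurations, a fixed-step
    Runge-Kutta / Euler-Maruyama integrator with delay-history lookup, the
    quadratic Lyapunov diagnostics of the synchronization error system
    (candidate function, its observed decay, the block stability matrix and
    its leading-principal-minors / symmetric-part eigenvalue tests),
    trajectory-bound estimation, synchronization metrics, trajectory export
    and error/phase-plane plots, plus a small command-line interface that
    reproduces the packaged five-neuron reference experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
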