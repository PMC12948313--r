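Package: hepacirc
Title: Closed-Loop Lumped-Parameter Cardiovascular Model with Hepatic Dual Blood Supply
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a closed-loop zero-dimensional (lumped-parameter)
    cardiovascular circuit comprising time-varying elastance ventricles,
    hyperbolic-tangent diode valves, three-element Windkessel (RCR)
    peripheral compartments, and a hepatic subsystem with dual blood supply
    (portal vein and hepatic artery converging in the sinusoids).  Provides
    integration to periodic steady state, pressure-volume-loop cardiac
    indices, Nelder-Mead calibration against healthy aortic pressure-flow
    targets, graded acute-liver-injury scenarios obtained by scaling hepatic
    microvascular resistances, and variance-based (Sobol') global
    sensitivity analysis of cardiac function with respect to hepatic
    resistances using Saltelli's sampling design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
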