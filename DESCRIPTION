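Package: borderzone
Title: Spiral and Scroll Wave Dynamics in a Recovering Ischaemic Border Zone
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of re-entrant electrical activity on the
    moving boundary of recovering ischaemic cardiac tissue.  Implements the
    Beeler-Reuter-Pumir neonatal myocyte model on resistively coupled 2D/3D
    cell networks with macroscopic gradients of coupling and excitability and
    frozen microscopic heterogeneity; phase-singularity (spiral tip) and
    scroll-filament detection; empirical estimation of the specific drift
    forces acting on spiral cores (electrophoretic/curvature-equivalent,
    excitability-gradient, and localized-inhomogeneity interaction); and the
    asymptotic drift ODE for pinning, tear-off and stability of pinned
    spirals.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
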