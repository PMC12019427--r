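Package: overstretch
Title: Coarse-Grained Langevin Simulation of dsDNA Overstretching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Bead-spring coarse-grained molecular dynamics of long
    double-stranded DNA under tension. Bonds between beads (11 bp each)
    follow a nonconvex stretching potential whose convex-hull (Maxwell)
    construction sets the overstretching plateau force; bending is a
    discrete worm-like chain; an optical trap is modelled as a stiff
    harmonic spring, approximating an isometric pulling experiment.
    Composite fragments built from segments with distinct plateau forces
    (poly(dA-dT), poly(dG-dC), torsionally constrained lambda-DNA) produce
    multiplateau force-extension curves. Includes the stretching protocol
    (one-phase starts over an extension grid, replicated equilibration and
    production averaging), bond-length distribution and phase analysis,
    and deterministic quasi-static and single-bond Gibbs references.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
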