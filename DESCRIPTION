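Package: solcable
Title: Quasi-Soliton Conduction of Electrotonic Signals in a Nonlinear Cable
    Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for a nonlinear core-conductor cable model of small
    neuronal branchlets in which polarization of the intracellular
    microstructure stores bound charge (charge 'soakage') and the outer
    mitochondrial membrane carries a quadratic, nonohmic current.  The
    model is a semilinear pseudo-parabolic cable equation whose
    travelling-wave reduction admits sech-squared quasi-soliton solutions
    with closed-form velocity and amplitude.  The package derives the
    dimensionless parameter groups from dimensional cable constants,
    evaluates the closed-form quasi-solitons and their travelling-wave
    residuals, superposes counter-propagating pulses for head-on collision
    analysis, integrates the full equation numerically by an implicit
    method of lines with the pseudo-parabolic mass operator treated
    exactly, and measures waves (peak tracking, two-point slope/velocity
    estimates, amplitude comparisons, collision elasticity) on either
    analytic or simulated fields.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
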