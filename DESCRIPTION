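Package: cgiter
Title: Iterative Structural Coarse-Graining of Pair Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives tabulated coarse-grained pair potentials that reproduce
    target radial distribution functions for molecular liquids and mixtures.
    Implements Newton and constrained Gauss-Newton updates whose Jacobians come
    from symmetry-reduced RISM integral equations with the hypernetted-chain
    closure, the inverse Monte Carlo Jacobian estimated from particle-count
    cross-correlations with an onset stabilization, and iterative Boltzmann
    inversion. Potential updates can be constrained to reproduce the virial
    pressure, Kirkwood-Buff integrals, or the intermolecular potential energy.
    A self-consistent RISM/HNC structure solver serves as a built-in forward
    model so the whole iteration loop runs without molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
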