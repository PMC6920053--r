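Package: crystdyn
Title: Collective Motions and Diffuse Scattering in Crystalline Protein Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of collective motions in coordinate ensembles of
    crystalline proteins. Computes trace-reduced C-alpha displacement
    covariance as a function of inter-atomic distance, partitions atom
    pairs into intraprotein and interprotein subsets, fits the
    exponential liquid-like motions (LLM) form a*exp(-r/gamma)+b, and
    subtracts rigid-body motions (RBM) model curves to isolate the
    short-range LLM component. Includes a synthetic crystal-ensemble
    generator with known LLM/RBM statistical structure, a rigid-body
    ensemble simulator, and a diffuse-scattering module that evaluates
    Guinier's equation (diffuse intensity as the variance of the
    structure factor) on a 3D reciprocal-space grid, with Laue
    symmetrization, anisotropic-component extraction, Bragg-neighborhood
    culling, and refinement of LLM and rigid-body-translation intensity
    models against a target lattice.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite,
    withr,
    yaml,
    bio3d
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
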