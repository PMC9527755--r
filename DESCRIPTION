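Package: biqens
Title: Bidisperse Protein Diffusion from Quasi-Elastic Neutron Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to separate the short-time self-diffusion coefficients of
    two label-free proteins (serum albumin and polyclonal immunoglobulin)
    from joint quasi-elastic neutron scattering (QENS) spectra. Provides a
    synthetic spectrum generator with the full statistical structure of a
    backscattering experiment (two-Gaussian resolution, D2O solvent line,
    Poisson counting noise), data reduction (empty-can subtraction,
    vanadium resolution fits, solvent fixing), Poisson maximum-likelihood
    q-wise and global spectral fits with monodisperse-average and
    bidisperse models, elastic incoherent structure factor and
    jump-diffusion analysis of the internal dynamics, and a bidisperse
    hard-sphere colloid theory chain (translational plus rotational
    short-time diffusion, apparent diffusion coefficients, renormalization
    to experimental volume-fraction scales) for comparison with the fits.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
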