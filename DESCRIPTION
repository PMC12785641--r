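Package: xtalgen
Title: Artificial Crystal Structure Generation for Phase-Problem Training Data
Version: 0.1.0
Authors@R: person("xtalgen", "developers", role = c("aut", "cre"),
    email = "xtalgen@example.org")
Description: Generates artificial triclinic (P-1 or P1) crystal structures and
    their diffraction data for training phase-problem solvers. Unit cells are
    derived from volumes sampled from a log-normal (or uniform) distribution,
    with bounded cell lengths and a maximum adjacent axis ratio; oblique cells
    are obtained by volume-preserving shear transforms with controlled angle
    distributions. Unit cells are filled either by uniform rejection sampling
    under a minimum-contact rule or by growing 'artificial molecules' bond by
    bond from covalent radii, with inversion-centre special positions
    pre-populated. Structure-factor amplitudes and exact centrosymmetric
    phases (0 or pi) are computed from four-Gaussian scattering factors with
    isotropic Debye-Waller attenuation. Includes the analytic probability
    density of the volume of a uniformly sampled orthorhombic cell, ensemble
    distribution validators, CIF and SHELX-style reflection output, and a
    seedable streaming batch generator with a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
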