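Package: ffval
Title: Statistical Validation of Protein Force Fields Against Structural and NMR Benchmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for benchmarking protein molecular-dynamics force fields
    against experimental reference structures. Ships a curated test set of 52
    high-resolution protein structures (39 X-ray, 13 NMR), computes a battery of
    structural metrics from conformational ensembles (backbone and native
    hydrogen bonds, polar and nonpolar solvent-accessible surface area, radius
    of gyration, Kabsch-Sander secondary structure, superposition RMSD and its
    size-normalised RMSD100, backbone dihedral distributions), back-calculates
    NMR observables (Karplus 3J-couplings, r^-3-averaged NOE distance
    violations with Wuthrich pseudoatom corrections), and decides whether
    alternative parameter sets differ significantly using nested mixed-effects
    models: Box-Cox preprocessing, univariate and multivariate likelihood-ratio
    tests, and Benjamini-Yekutieli adjusted pairwise contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    MASS,
    nlme,
    lme4,
    emmeans,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
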