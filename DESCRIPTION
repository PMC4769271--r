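Package: ompath
Title: Conformational Transition States from Onsager-Machlup Action
    Minimization over Anisotropic Network Wells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the most-probable transition path and the transition
    state between two equilibrium protein structures by minimizing the
    Onsager-Machlup action over a double harmonic well built from
    anisotropic network models (ANM) of the two end states.  The barrier
    time is estimated non-iteratively from the average force constant of
    each well, the two trajectory branches are matched by velocity
    continuity at the cusp, and the invariant leading and trailing
    portions of the path are truncated.  Includes an exact one-dimensional
    diatomic reference model with its convergence surface, trajectory
    energy profiling against external paths, free-energy-surface binning
    and fitting over two collective variables, and seeded synthetic
    two-state structure generators for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    jsonlite
Config/testthat/edition: 3
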