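Package: pmfsurf
Title: Potential of Mean Force Surfaces for Nanocrystal Adsorption at
    Liquid-Liquid Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs two-dimensional adsorption free-energy surfaces
    (potentials of mean force) from gridded mean-force and mean-torque
    samples by boundary thermodynamic integration and iterative relaxation
    of the discrete gradient-consistency equations, with a direct sparse
    least-squares solver for cross-checking.  Extracts adsorption states
    (local minima), transfer free energies and minimax barrier heights
    from the fitted surface.  Companion tools analyse the thin water layer
    that stabilises adsorbed states: dipole orientation distributions with
    exact sin(theta) Jacobian correction, and anisotropic self-diffusion
    from per-axis mean-square displacements of gap-resident molecules.
    Fully seeded synthetic generators (analytic multi-well surfaces with
    noisy gradient samples, AR(1) force/torque time series, and
    gap-confined Brownian water trajectories) provide ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
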