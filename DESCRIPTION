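Package: osteorom
Title: Bone Remodelling Around Hip Implants with a POD-RBF Reduced-Order Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates strain-energy-driven bone remodelling around a
    repositioned hip implant and builds a non-intrusive reduced-order
    surrogate for the converged bone-mass-density (BMD) field. A
    parameterised reference simplex mesh is morphed for new implant poses
    by solving Laplace's equation with a precomputed static-condensation
    operator, a gradient-enhanced finite-element remodelling solver
    produces high-fidelity BMD snapshots, and proper orthogonal
    decomposition combined with radial basis function interpolation
    (POD-RBF) predicts full BMD fields for unseen implant poses in
    milliseconds. Includes synthetic reference-domain generation,
    sampling plans, Spearman sensitivity diagnostics, region-wise mass
    accounting, and VTK export of fields.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    graphics,
    stats,
    utils,
    withr
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
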