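Package: voromech
Title: Voronoi Cell Mechanics and Fiber Orientation Analysis for Confined
    Cell Monolayers
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates confined cell monolayers with a Voronoi-cell
    mechanical model in which cells carry an isotropic prestretch
    (condensation tendency) and boundary cells a stiffness or contractility
    differential, and relaxes cell centers to mechanical equilibrium by
    gradient flow through the dual Delaunay triangulation. Provides the
    accompanying morphometric readouts (cell shape tensor, elongation,
    angle deviation from the radial direction, per-cell stress tensor and
    principal strains), image-side fiber-orientation quantification
    (structure-tensor orientation fields, the alignment structure
    parameter, radial profiles, image stacking) with a synthetic
    fiber-image generator for validation, a parameter-sweep driver, and a
    cantilever-beam micropost traction-force utility.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    interp,
    jsonlite,
    yaml,
    stats,
    utils,
    tiff,
    png,
    EBImage
Suggests:
    deldir,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
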