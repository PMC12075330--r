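Package: prepvol
Title: Parametric Tooth-Preparation Geometry and Volumetric Substance Removal
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Digital generation of parametric tooth-preparation geometries
    (chamfer finish-line profile swept along the preparation margin, Boolean
    subtraction of axial and occlusal cutter solids, seam smoothing) and
    quantification of volumetric tooth-substance removal relative to the
    intact crown. Ships watertight synthetic tooth fixtures with annotated
    cementoenamel-junction curves (analytic cylinder and frustum shapes with
    closed-form volumes, and a molar-like fixture with cusps and a non-planar
    CEJ), a triangle-mesh kernel (STL/OBJ input and output, divergence-theorem
    volumes, watertightness diagnostics, a voxel volume oracle), and a
    factorial study layer that sweeps preparation angle, chamfer depth,
    finish-line distance above the CEJ and occlusal reduction, summarising
    per-step removal increments, parameter effect ranking and
    material-specific preparation comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
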