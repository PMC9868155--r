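Package: airwayloss
Title: Pharyngeal Pressure-Loss Analysis of Upper-Airway Surface Meshes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify inspiratory pressure loss in the pharyngeal
    airway from triangulated surface meshes. The package slices an airway
    surface mesh into a stack of cross-sectional planes, computes
    cross-sectional areas and minimum-area (plane_Amin) morphometry, runs a
    quasi one-dimensional extended Bernoulli flow model with Darcy friction
    and Borda-Carnot expansion losses, computes mass-flow-weighted plane
    averages of static pressure, velocity and turbulence kinetic energy,
    derives dynamic/total/relative total pressure, subsegmental loss
    coefficients and resistances, aggregates wall shear stress, splits the
    total-pressure loss into frictional and interior (separation) components,
    and classifies the airway into jet-formation, pre-separation and full
    flow-separation levels. A parametric generator of hourglass-shaped
    pharyngeal lumens and jet/recirculation flow fields makes the entire
    pipeline testable without patient imaging or a 3D CFD solver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
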