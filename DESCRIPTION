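Package: fibriflex
Title: Hinge-Bending Flexibility and Adsorption Modelling of Fibrinogen
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the internal dynamics of fibrinogen and
    similarly hinged multi-domain proteins. Computes hinge bending and torsion
    angles from C-alpha trajectories, principal component analyses with
    subspace-overlap comparisons, and helicity statistics around plasmin
    cleavage sites; provides a coarse-grained rod-and-sphere Monte Carlo model
    of adsorption on a flat surface with maximum-entropy fitting of hinge-weight
    models to AFM-style angle histograms; builds linear-mutual-information
    correlation networks with shortest-pathway and bottleneck analysis; and
    includes synthetic-data generators so every stage is testable without
    molecular-dynamics output or experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
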