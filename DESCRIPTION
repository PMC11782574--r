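Package: foldax
Title: Coupled Simulation of Cortical Folding and Axon Bundle Pathfinding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates gyrification of a two-dimensional growing bilayer
    (a tangentially growing cortical plate on a white-matter substrate,
    modelled with multiplicative morphoelastic growth and a compressible
    neo-Hookean law, relaxed quasi-statically by explicit dynamics) coupled
    to discrete axon-bundle agents that elongate stochastically, accelerate
    under axial tension, reorient toward the maximum tensile principal
    stress of the extracellular matrix, and stiffen the substrate by
    converting the elements they traverse into fiber elements. Includes the
    quantitative readouts used to characterise the outcome (gyrification
    index, gyral and sulcal fiber densities, fiber volume fractions, local
    and equivalent stiffness ratios, angular distributions), conversions of
    literature neurite elongation rates to a stress-dependent elongation
    rate, analytic stress-field fixtures for testing the agent model
    without finite elements, and VTK/CSV/JSON/YAML input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
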