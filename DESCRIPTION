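Package: stentCA
Title: Stochastic Cellular-Automaton Corrosion Model for Coated
    Magnesium-Alloy Stent Struts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the biodegradation of polymer-coated magnesium-alloy
    stent struts with a stochastic cellular automaton over a layered
    strut-cross-section lattice. Crimp-expansion deformation is represented
    by an analytic strain surrogate whose peak strains drive local coating
    porosity and through-thickness cracking; random-walking corrosive
    species (water, chloride, protons) then dissolve the fluoride and oxide
    conversion layers and convert the magnesium substrate to hydroxide
    product. Ships presets contrasting a low-elongation (PDLLA) and a
    high-elongation (PBAT) coating, per-component degradation traces and
    rate profiles overall and in the high-strain arc region, milestone
    detection, a calibration routine for the free reaction probabilities,
    and deterministic lattice renderers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    yaml,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
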