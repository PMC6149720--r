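Package: lamellar
Title: Lamellar Neutron Diffraction Reduction and Bilayer Structure Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reduction and analysis of small-angle neutron diffraction data
    from aligned lipid multilayers. Converts rocking-scan peak tables into
    indexed, corrected structure factors, assigns phases by D2O/H2O contrast
    variation, reconstructs one-dimensional neutron scattering length density
    profiles by Fourier synthesis, and derives bilayer structural parameters
    (lamellar repeat distance, head-to-head distance, Gibbs bilayer thickness,
    water layer thickness, area per unit cell). Includes a forward model of a
    centrosymmetric fluid-phase bilayer for end-to-end validation by parameter
    recovery, and trajectory observables for coarse-grained membrane
    simulations (P2 bond order parameters, number density profiles,
    phosphate-to-phosphate thickness, lateral radial distribution functions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
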