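Package: cscmc
Title: Charge-Space Competition Monte Carlo for Cation Channel Selectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Grand-canonical Monte Carlo simulation of cation selectivity in
    ion-channel selectivity filters with the charge-space competition (CSC)
    model.  The pore wall is built from the crystallographic positions of the
    selectivity-filter lining atoms, represented as harmonically tethered hard
    spheres whose spring constants derive from X-ray B-factors.  Electrostatics
    combine direct Coulomb interactions in a uniform aqueous dielectric with
    the induced surface charge on the sharp protein/water dielectric boundary,
    solved by a boundary-element collocation method.  Cation hydration is
    modelled as a set of discrete hard-sphere hydration states with
    Boltzmann-weighted bulk population factors and a grand-canonical
    hydration-swap move.  Selectivity is estimated from axial concentration
    profiles via density minima at the rate-determining barrier.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    bio3d,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
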