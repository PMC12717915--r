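Package: vibromix
Title: Vibronic Lineshapes, Dye Dimerization Equilibria and Nanocavity
    Strong Coupling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models the absorption lineshape of cationic dyes such as
    methylene blue. Computes finite-temperature Franck-Condon vibronic
    stick spectra for harmonic ground and excited surfaces in the
    independent-mode (adiabatic Hessian) approximation, broadens them
    with Gaussians and locates peaks and shoulders; solves the
    monomer-dimer equilibrium and superposes monomer and H-aggregate
    dimer spectra into composite solution spectra, with nonlinear
    least-squares recovery of the dimerization constant from dilution
    series; and simulates plasmonic nanocavity extinction spectra with a
    classical input/output coupled-oscillator model, reporting Rabi
    splitting and polariton asymmetry. Seeded synthetic-data generators
    provide every input the pipeline needs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
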