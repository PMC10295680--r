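Package: crocinrad
Title: Radiolytic Kinetics, Spectral Calibration and Simulated Spectra for
    Crocin Oxidation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the hydroxyl-radical oxidation of the saffron
    carotenoid crocin as observed by pulse and steady-state (gamma) radiolysis.
    Implements radiolytic G-value bookkeeping and dosimetry from hydrated
    electron absorbance, pseudo-first-order and second-order transient
    absorbance fitting, isosbestic-anchored molar-absorptivity calibration of
    the oxidized radical, its covalent dimer and the final twice-oxidized
    product, two-component dose-series deconvolution with mass balance,
    conversion of quantum-chemical electronic transition line lists into
    UV-vis spectra with spin-contamination screening and probability-weighted
    species mixing, a Metropolis Monte Carlo engine with multi-stretch and
    torsional moves for polyene conformer sampling, Wertz-corrected
    association free energies and redox-potential arithmetic, and synthetic
    data generators emulating the experimental inputs so that every stage can
    be exercised without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
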