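Package: sdhcl
Title: Chloride Homeostasis Modelling and Quantification in the Spinal Dorsal Horn
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Biophysical modelling and analysis tools for studying chloride
    homeostasis in superficial dorsal horn neurons. Provides
    Goldman-Hodgkin-Katz and Nernst ionic primitives with a saturating KCC2
    co-transporter flux, a single-compartment Morris-Lecar simulator of
    membrane potential, intracellular chloride and extracellular potassium
    under stochastic synaptic bombardment, a reduced finite-volume model of
    the pipette-imposed chloride load used to estimate extrusion capacity,
    analysis operators for GABA-A reversal potentials, evoked IPSC train
    depression and charge transfer, fluorescence-lifetime (Stern-Volmer)
    chloride estimation, laminar immunofluorescence quantification (IB4
    barycentric axis, trans-laminar profiles, membrane indices) and
    immunogold particle clustering, plus seeded synthetic-data generators
    for every input type.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
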