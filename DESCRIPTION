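Package: mesokit
Title: Multi-Modal Analysis of Lipidic Mesophases Across Phase Transitions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to characterise lyotropic lipidic mesophases with and
    without excess water from three experimental modalities. Indexes 1-D
    small-angle X-ray scattering (SAXS) powder patterns against Bragg
    spacing-ratio rules for cubic (Pn3m, Ia3d, Im3m), reverse hexagonal
    (HII) and lamellar phases, fits lattice parameters, and builds
    temperature-composition phase diagrams including the excess-water
    swelling boundary. Fits broadband dielectric spectra with sums of
    Havriliak-Negami relaxation processes plus dc conductivity, in either
    the dielectric-loss or loss-tangent representation, extracts relaxation
    times at maximum loss, and assembles Arrhenius relaxation maps with
    piecewise-linear kink detection at phase transitions. Deconvolves FTIR
    regions (lipid headgroup, ester carbonyl, CH stretch, OH stretch) into
    Gaussian sub-bands, computes hydrogen-bond water-population fractions
    and the free to H-bonded carbonyl ratio, and tracks band-centre trends
    with breakpoint detection. A synthetic-data module generates internally
    consistent SAXS/dielectric/FTIR temperature series from declarative
    ground-truth scenarios for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
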