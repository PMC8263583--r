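Package: hepchip
Title: Biophysical Design Analysis for a Hepatic-Cord Liver-on-Chip
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Lumped-parameter and depth-averaged transport models for a
    multiplexed liver-sinusoid-on-chip in which rows of hepatocyte culture
    chambers communicate with a perfused medium channel through arrays of
    micrometre-scale slits. Provides a Kirchhoff hydraulic-resistance
    network solver for the chip and its external capillary resistor, wall
    shear stress estimation at cell positions, a finite-volume steady
    advection-diffusion solver for oxygen with Michaelis-Menten cellular
    uptake and permeation through the gas-permeable chip ceiling, analytic
    oxygen budgets, determination of the admissible operating flow window
    (shear ceiling, hypoxia floor), capillary resistor selection against
    pressure disturbances, and seeded synthetic generators for per-chamber
    cell occupancy and Monte-Carlo parameter sensitivity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
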