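Package: mpsflow
Title: Hydraulic, Mechanical and Barrier-Function Models for Two-Channel
    Membrane Microphysiological Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reduced-order design and analysis toolkit for two-channel
    organ-on-chip devices separated by a porous membrane. Implements a
    lumped-parameter hydraulic network of the chip (channel and membrane
    resistances by the hydraulic-electric analogy, wall shear stress,
    steady transmembrane ultrafiltration), bi-axial membrane strain from
    measured deflection via a semi-ellipsoid surface-area model,
    pneumatic pump waveform generation, and barrier-function assay
    analytics (TEER by the Ohm's-law method, clearance-based filtration
    with blank normalization). Seeded synthetic-data generators emulate
    every instrument readout the analyses consume, so the full pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
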