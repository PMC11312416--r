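Package: cryopvi
Title: Bioheat Simulation of Cryoballoon Pulmonary Vein Isolation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Axisymmetric finite-volume solver for the Pennes bioheat
    equation tailored to cryoballoon ablation of the pulmonary veins.
    Converts per-patient therapy logs (thermocouple time/temperature
    milestones) into a two-cycle balloon surface-temperature schedule,
    integrates freezing and thawing through layered vein geometry
    (lumen, vascular wall, pulmonary tissue), extracts isotherm fronts,
    and estimates elliptical lesion cross-section area together with
    cohort summary statistics. Includes closed-form verification
    oracles, energy-conservation and grid-convergence checks, a
    synthetic therapy-log generator, and CSV/VTK/JSON export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    grDevices,
    graphics,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
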