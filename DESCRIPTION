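Package: aureole
Title: Spreading Dynamics and Collective Microparticle Uptake of Cell
    Aggregates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and measures the wetting-like spreading of 3D cell
    aggregates on substrates carpeted with sedimented microparticles.
    Implements the diffusive spreading law of the cellular precursor film,
    the velocity enhancement by substrate roughness, and a particle
    conservation model that converts the geometry of the dark "aureole" of
    particle-laden peripheral cells into per-cell internalized and adsorbed
    particle counts. Ships a synthetic-data generator (noisy spreading
    trajectories, a discrete front-uptake simulator, bright-field-like
    micrograph and confocal-like Z-stack renderers with known ground truth),
    automated image measurements of film area, aureole width, surface
    fraction and Z-stack volume fractions, and least-squares fits that
    recover the model parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
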