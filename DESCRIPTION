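Package: lenselast
Title: Compression Optical Coherence Elastography and Inverse Modeling of the Crystalline Lens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative compression optical coherence elastography
    (OCE) of the ex vivo crystalline lens. Provides a seeded synthetic-data
    generator for complex-valued B-scan stacks and force-relaxation traces,
    phase-sensitive complex cross-correlation processing into axial
    displacement and strain maps, reflectivity-based segmentation of
    cortical and nuclear regions, a quasi-1D visco-hyperelastic
    (Neo-Hookean with one-term Prony series) forward model of lens
    compression, inverse parameter identification through full-factorial
    response surfaces, and group-comparison statistics for preservation
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tiff,
    rhdf5
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
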