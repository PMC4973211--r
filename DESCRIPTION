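Package: stillindex
Title: Indexing of Still-Shot Protein Crystal Diffraction Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Determines crystal orientation matrices from the Bragg spot
    centroids of still diffraction images (serial synchrotron and XFEL
    crystallography), given known unit-cell and space-group priors. Spots are
    back-projected onto the Ewald sphere and all inter-spot difference vectors
    that match theoretically allowed lattice vectors in length are used to
    build candidate orientations, either by clustering rotation matrices or by
    growing self-consistent vector networks, with support for multiple
    lattices per image. One-dimensional pseudo-powder patterns of inter-spot
    distances diagnose and correct detector-distance and wavelength errors.
    A seeded synthetic still-image simulator provides ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
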