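Package: stereocal
Title: Geometry Calibration of Stereo Cone-Beam X-ray CT Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Phantom-based geometric calibration for modular stereo (dual
    source/detector) cone-beam X-ray CT systems. Provides a 21
    degree-of-freedom parametric forward model of a stereo acquisition
    geometry, a brick-lattice fiducial phantom builder, an analytic
    radiograph simulator for attenuating spherical markers, sub-pixel bead
    detection via template matching and intensity-weighted centroids, and a
    staged bound-constrained minimization of the reprojection cost that
    estimates phantom pose, detector poses, source distance offsets and the
    stereo angle. Calibrated geometries can be exported as per-view
    cone-beam vectors for external reconstruction engines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    clue,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
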