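Package: smfoci
Title: Single-Molecule Quantification of Fluorescent Protein Foci in Live Bacteria
Version: 0.1.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of single-molecule live-cell
    fluorescence movies of rod-shaped bacteria. Generates synthetic
    two-colour movies (rapid acquisition and time-lapse) of a DNA-damage
    inducible, fluorescently tagged DNA polymerase together with replisome
    markers, with full ground truth. Provides image correction, cell
    segmentation and geometry (spherocylinder volumes), focus detection and
    elliptical 2D Gaussian fitting, background-ring corrected intensity
    trajectories, per-cell copy numbers and concentrations from
    two-exponential photobleaching decays with single-molecule intensity
    calibration, change-point step counting for molecules per focus, and
    two-channel colocalisation statistics (equal-area shell histograms,
    thresholded bidirectional fractions, chance levels from disc-union
    area fractions) with time-resolved uncertainty.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
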