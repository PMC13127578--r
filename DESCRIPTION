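Package: qxlms
Title: Quantitative Cross-Linking Mass Spectrometry Differential Dynamics Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for label-free quantitative cross-linking mass
    spectrometry (qXL-MS) analysis of protein conformational dynamics.
    Normalizes replicate MS1 intensities by total unreacted-peptide signal,
    aggregates peptide-level signal to residue-resolved cross-links and
    monolinks, calls differential abundance between two conditions with a
    one-tailed homoscedastic t-test and fold-change thresholds, maps
    significant links onto atomic models against the 30-Angstrom DSBU
    Calpha-Calpha reach criterion, and classifies each link into
    conformational-dynamics categories. Also provides structural-geometry
    measurements (Kabsch superposition, per-residue deviations, segment
    rotation angles, atom-pair distances, interface polar contacts) and
    synthetic-data generators with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
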