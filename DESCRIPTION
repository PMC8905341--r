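Package: trabkit
Title: Contractility, Pacing, Imaging and Molecular Analysis for Cultured Cardiac Trabeculae
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for long-term cultures of human atrial
    trabeculae kept under electrical field stimulation. Detects contractions
    in twitch-force recordings and measures per-beat kinetics (diastolic
    force, amplitude, TTP90, TTR90, CD90), derives the mechanical refractory
    period and maximum captured frequency from S1-S2 extrastimulus and
    frequency-ladder pacing protocols, co-analyses synchronized calcium
    photometry and force, segments 3D confocal stacks of immunostained
    myocardium (depth correction, Richardson-Lucy deconvolution, watershed
    cell partitioning, myocyte classification, volume fractions), and
    computes efficiency-corrected qPCR expression ratios and MTT/Bradford
    viability statistics. A synthetic-data generator with a restitution-based
    excitation model emulates every raw input kind with known ground truth so
    each stage can be validated by parameter recovery.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    tiff,
    rlang,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
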