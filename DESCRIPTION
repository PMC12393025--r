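Package: NemaTrack
Title: Quantification of C. elegans Locomotion, Body Posture, Sleep and
    Action Potentials
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An offline toolkit for quantitative analysis of Caenorhabditis
    elegans behavior and electrophysiology. Segments single worms from
    grayscale image sequences, fits a 13-marker midline spline with
    automatic threshold retry, and merges poses with motorized-stage logs
    into absolute-coordinate tracks. Derives locomotion metrics (speed,
    distance, directionality, amplitude/length), signed bend-angle traces
    with RMS bend and dominant undulation frequency, inflection-bounded
    body-curvature segments via Kasa least-squares circle fitting,
    sleep-like quiescence bouts from centroid displacement series, and
    action-potential properties (threshold by two methods, RMP, amplitude,
    APD50, AHP, rise/decay times, phase-plot slopes) from current-clamp
    voltage traces. Ships ground-truthed synthetic generators for rendered
    worm images, crawl recordings, sleep actograms and AP trains, so every
    analysis path is testable without microscope or amplifier hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
biocViews: Software, CellBasedAssays, Visualization, Electrophysiology
RoxygenNote: 7.3.3
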