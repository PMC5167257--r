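Package: KymoTrack
Title: Automated Kymograph Construction, Multi-Peak Tracking and Motility Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds kymographs (space-time plots) from multi-page TIFF
    fluorescence time-series along user-supplied lines of interest, segments
    each kymograph row with Otsu's method, detects intensity peaks (local
    maxima or one-dimensional watershed) or object edges (one-dimensional
    Canny), links peaks across time by distance minimization with angle-based
    tie-breaking, prunes short and redundant tracks, and detects track
    split/merge (branch) events. Computes per-step and per-track motility
    statistics (displacement, velocity, speed, tortuosity), normalized
    intensity traces, exponential-decay fits of velocity and error
    distributions, and single-phase exponential assembly kinetics. Includes a
    synthetic fluorescent-bead simulator (disk/averaging-filtered point
    sources, optional 1-D Gaussian random walk, additive Gaussian noise) with
    ground truth, so sub-pixel positional accuracy of the tracking pipeline
    can be quantified without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tiff,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    pracma,
    EBImage,
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'KymoTrack-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'io.R'
    'kymograph.R'
    'detection.R'
    'tracking.R'
    'statistics.R'
    'synthetic.R'
    'pipeline.R'
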