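Package: gssp
Title: Gaze Self-Similarity Plots and Texture Metrics for Eye-Movement Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds gaze self-similarity plots (GSSP) from raw eye-tracking
    recordings: n-by-n matrices of normalized pairwise distances between gaze
    samples, plus a directed variant that stores signed horizontal distances in
    the upper triangle and signed vertical distances in the lower one.
    Matrices can be rendered as grayscale or red/green images, quantified with
    co-occurrence-matrix texture metrics (homogeneity, contrast, uniformity),
    and analysed in a moving window over long recordings. A directed matrix
    together with one anchored gaze point suffices to reconstruct the original
    scan-path. Synthetic gaze generators (fixation/saccade sequences, smooth
    pursuit, forward and backward reading, outlier injection) make the whole
    pipeline testable without recordings, and a command-line entry point binds
    the pieces together.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    data.table,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
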