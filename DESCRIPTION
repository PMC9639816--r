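Package: semgfusion
Title: Multi-Stream Feature-Fusion Networks for Surface-EMG Gesture Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for intrasubject hand-gesture recognition
    from multichannel surface electromyography (sEMG) recorded under the
    NinaPro acquisition protocol (12 electrodes, 2000 Hz, six repetitions per
    gesture).  Provides a reader for NinaPro-layout MATLAB files, a synthetic
    recording generator that emulates the acquisition protocol, fourth-order
    Butterworth band-pass denoising, rest-separated action segmentation,
    per-channel Z-score normalisation, overlapping sliding-window
    fragmentation, time-warping data augmentation, a multi-stream
    convolutional network with residual channel/spatial attention and
    early/late feature fusion, and a repetition-wise cross-validation
    training and evaluation harness.  The network engine (2-D convolution,
    batch normalisation, attention blocks, Adam) is implemented in base R on
    top of BLAS matrix products, so the whole pipeline runs on one CPU with
    no external deep-learning framework.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
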