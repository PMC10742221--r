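Package: eegskill
Title: EEG Topographic Classification of Surgical Skill
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Two complementary pipelines for classifying bimanual-task expertise
    from multichannel scalp EEG. The first branch segments task-onset EEG into
    polarity-invariant microstates (modified K-means on global-field-power peak
    maps, model selection by a cross-validation criterion) and feeds
    microstate-conditioned, Tikhonov-regularized common spatial patterns into a
    linear discriminant classifier. The second branch converts EEG into
    topography-preserving 16x16xT tensors (azimuthal equidistant projection,
    biharmonic spline interpolation) classified by a small 3-D convolutional
    network with temporal attentive pooling, inspected post hoc with
    gradient-weighted class activation mapping. Includes readers/writers for
    BrainVision and EDF+ recordings, a standard preprocessing chain (polyphase
    resampling, zero-phase FIR high-pass, line-noise regression, bad-channel
    detection and spherical-spline interpolation, artifact subspace
    reconstruction, surface Laplacian), and a synthetic-data generator that
    plants group-specific scalp topographies for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    Matrix,
    signal,
    pracma,
    mgcv,
    tibble,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
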