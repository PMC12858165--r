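Package: hfbEncode
Title: Encoding Models of High-Frequency-Band iEEG Responses to Facial
    Emotion Features
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for fitting lagged linear encoding models that predict
    high-frequency-band (110-140 Hz) intracranial EEG amplitude from
    continuous facial-emotion feature time courses during naturalistic
    audiovisual stimulation. Implements the full pipeline: notch filtering,
    common-average referencing, Butterworth band-pass plus Hilbert analytic
    amplitude extraction, block epoching, anti-aliased downsampling,
    square-root transform and baseline z-scoring; feature aggregation over
    faces, 2 Hz bin-average resampling and lagged design-matrix
    construction; ridge regression with fivefold cross-validation and a
    single regularization coefficient shared across subjects, regions and
    conditions; temporal-shuffle permutation inference and parametric group
    contrasts; absolute-weight summaries grouped into complex and basic
    emotions and correlated with age. A synthetic-data generator emulates
    the 13-block speech/music stimulus structure with known ground-truth
    coupling so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'config.R'
    'AllGenerics.R'
    'encoding.R'
    'features.R'
    'io-edf.R'
    'io.R'
    'preprocess.R'
    'simulate.R'
    'stats.R'
    'utils-dsp.R'
    'weights.R'
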