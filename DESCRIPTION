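Package: sportdwt
Title: Sporting-Activity Classification from Smartphone Accelerometers via
    Wavelet Energy Features
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies field-sport activities (stationary, walking, jogging,
    sprinting, ball hits, tackles, dribbling) from tri-axial smartphone
    accelerometer logs. Windows centred on an annotated activity are
    decomposed with a periodized discrete wavelet transform (49 mother
    wavelets across the Haar, Daubechies, Coiflet, Symlet, biorthogonal and
    reverse biorthogonal families), summarised as energy-distribution ratios
    and normalized coefficient variances (6(1+i) features at level i), and
    fed to one of five classifier families (linear SVM, k-nearest neighbour,
    Gaussian naive Bayes, logistic model tree, multilayer perceptron) or to a
    maximum-confidence fusion of per-activity one-vs-rest models. Includes
    the full evaluation protocol (repeated stratified holdout, stratified
    k-fold cross-validation, macro F-measure, per-class-probability mean
    absolute error, parameter sweeps over wavelet, level, window length and
    classifier) and a seeded synthetic-session simulator for two device
    profiles so the pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    graphics,
    nnet,
    rpart,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
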