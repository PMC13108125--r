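Package: FoveatedVision
Title: Foveated Log-Polar Retinotopy for Image Classifiers: Transforms,
    Geometric Attacks and Fixation-Based Localization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a foveated retinotopic (log-polar) preprocessing
    transform for raster images with a movable fixation point, together with
    the evaluation machinery built on it: rotation, zoom and wraparound
    translation operators with their analytic log-polar shift predictions;
    worst-case geometric attack protocols and accuracy sweeps against any
    classifier exposing a probability-vector contract; fixation-grid
    likelihood (saliency) maps for visual search with saccade selection,
    recentering, aggregation and map algebra; localization metrics (pointing
    game, in/out activation ratio, IoU curves, keypoint Gaussian heat maps);
    and a deterministic synthetic-scene generator plus a small convolutional
    classifier harness so every pipeline stage is testable on one CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, jsonlite, png
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'sampling.R'
    'retinal_mapping.R'
    'geometric_transforms.R'
    'classifier.R'
    'toy_cnn.R'
    'attacks.R'
    'likelihood_maps.R'
    'localization_metrics.R'
    'synthetic_data.R'
    'io.R'
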