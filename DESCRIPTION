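Package: aoqc
Title: Image Quality Grading for Adaptive Optics Retinal Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quality-control toolkit for flood-illumination adaptive optics
    (AO-FIO) images of the cone photoreceptor mosaic.  Scores 50x50 micrometre
    sampling windows with the energy-of-Laplacian (LAPE) focus operator,
    classifies them into three quality categories with either LAPE-threshold
    classifiers (linear-regression rounding; random forest with
    probability-curve threshold extraction) or a compact convolutional neural
    network, and provides the manual-grading machinery these automated graders
    are validated against: multi-grader adjudication, Cohen's kappa, confusion
    matrices, subject-wise cross-validation, and a logistic-regression
    analysis of the subject, eye and location factors that drive poor image
    quality.  Includes a synthetic cone-mosaic generator with planted
    ground-truth categories for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ranger,
    EBImage,
    tiff
Suggests:
    testthat (>= 3.0.0),
    e1071,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
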