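Package: deeplof
Title: Anomaly Detection on Deep Feature Descriptors for Small Imbalanced Image Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage discrimination of a rare, heterogeneous "abnormal" image
    class from a common "normal" class in small, imbalanced paired-image
    cohorts (for example T1/T2-weighted MRI tumor crops). Paired grayscale
    images are fused into pseudo-color inputs, a convolutional network is
    trained with the L2-constrained softmax loss on three classes (normal,
    abnormal, auxiliary non-medical texture), and Local Outlier Factor
    scoring of the penultimate-layer feature descriptors converts the
    problem into novelty detection. Includes a synthetic cohort generator
    emulating the imbalanced study design, a training-time augmentation
    stack (flips, rotation, random erasing, mixup), ROC and precision-recall
    evaluation with Youden operating points, DeLong and bootstrap confidence
    intervals, and an ablation-ladder experiment driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    EBImage,
    png
Suggests:
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
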