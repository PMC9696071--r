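Package: dentalseg
Title: Cascade Attention Networks for Multi-Class Dental Lesion Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trainable three-branch cascade segmentation networks for intraoral
    photographs with five pixel classes (background plus calculus, gingivitis,
    tartar and worn enamel surfaces). Provides an improved image cascade
    network (ICNet) with convolutional block attention (CBAM) whose spatial
    attention uses stacked dilated 3x3 convolutions, asymmetric (k x 1 then
    1 x k) convolution factorization, cascade feature fusion with auxiliary
    deep supervision, a weighted multi-branch cross-entropy loss, automatic
    color equalization (ACE) preprocessing for overexposed images, confusion
    matrix based evaluation metrics (pixel accuracy, mean IoU, macro F1), a
    seeded synthetic intraoral scene generator with class-imbalanced lesion
    masks, and a train/evaluate/predict pipeline with a brightness-robustness
    evaluation mode. The network engine (convolution, normalization,
    attention, bilinear resampling and their reverse-mode gradients) is
    implemented in R with Rcpp kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
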