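Package: penreg
Title: Two-Camera Deformable Registration of Livestock Pen Video Frames
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Registers co-temporal video frames from two overlapping cameras
    observing the same livestock pen. Raw frames are corrected for radial
    lens distortion, masked to the pen and converted to grayscale, then
    pre-registered with a landmark-fitted projective transform. A U-Net
    style convolutional network predicts a dense per-pixel displacement
    field that refines the linear alignment; it is trained unsupervisedly
    with an image-similarity plus diffusion-regularization loss through a
    differentiable spatial-transformer warp, and fine-tuned
    semi-supervisedly with a small set of annotated landmark pairs.
    Registration quality is evaluated by target registration error (TRE)
    with foreground/background breakdown and paired statistical tests.
    A synthetic paired-view scene generator with known ground-truth
    geometry makes every stage trainable and testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    png,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    tiff,
    EBImage,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
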