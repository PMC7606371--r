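Package: dmriqa
Title: Hierarchical No-Reference Image Quality Assessment for Diffusion MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Automated, no-reference quality assessment of diffusion MRI at
    slice, volume, and subject level. A slice-wise quality network built from
    depthwise-separable residual and nonlocal residual blocks rates each
    sagittal slice pass/questionable/fail; slice features are agglomerated by
    a volume-wise network, and subject ratings follow from decision rules.
    Training tolerates small and noisy annotation sets through semi-supervised
    pseudo-labeling and iterative slice/volume self-training. Includes a
    synthetic artifact simulator (ghosting, signal dropout, blur, Rician
    noise) so the full pipeline can be exercised without access to clinical
    data, plus confusion-matrix metrics (per-class sensitivity/specificity,
    overall accuracy) and tidy/ggplot2 reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    RNifti,
    Rcpp,
    stats,
    tibble,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
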