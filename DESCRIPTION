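Package: templateprobe
Title: Template Perturbation and Accuracy Metrics for Protein Structure
    Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for probing protein structure predictors with
    deliberately degraded or perturbed structural templates, and for
    scoring any model against a reference structure.  Implements
    side-chain stripping with three C-beta placement policies,
    glycine-C-beta template construction, Gaussian coordinate noise,
    projection onto leading principal components, and homology-hit
    filtering, together with a metric suite comprising TM-score, Kabsch
    RMSD, rectified C-alpha RMSD, the local distance difference test
    (lDDT), side-chain chi-angle mean absolute error, and burial
    stratification.  An idealized all-atom structure generator lets every
    stage be exercised without external data.
License: MIT + file LICENSE
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
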