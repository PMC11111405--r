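Package: facegeom
Title: Population Geometry of Familiar-Face Coding in Face Patches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how familiar faces are encoded by neural
    populations that carry a linear axis code for facial features. Includes a
    synthetic generator of face spaces and Poisson spiking populations with
    switchable familiarity effects (an early orthogonal subspace shift, a
    long-latency axis rotation, gain and temporal-context modulation);
    estimators of per-cell preferred axes with split-half reliability;
    time-resolved comparisons of axes fit on unfamiliar versus familiar faces;
    population-geometry analyses (representational similarity, feature and
    familiarity decoding, centroid distances, d-prime with shuffle nulls,
    familiarity-axis orthogonality, condition contrasts); and
    distribution-matched stimulus subset selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
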