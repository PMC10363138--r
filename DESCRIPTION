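Package: toothprep
Title: Automated Geometric Evaluation of Tooth Preparations for Single Crowns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Software-based automated evaluation of abutment tooth preparations
    for single-unit crowns from registered pairs of 3D surface scans (intact
    anatomical tooth and prepared abutment). Detects the preparation margin as
    a closed feature line using cotangent-Laplacian sharpness and
    sharpness-adjusted shortest paths, partitions the abutment into margin
    band, axial quadrants and occlusal reduction area, measures cusp
    reductions, area-weighted axial tapers and total occlusal convergence,
    margin-band width, grades the measurements against an explicit rubric with
    color-coded mesh output, and computes rater-agreement statistics
    (Cronbach's alpha, weighted Cohen's kappa). Includes STL/PLY mesh I/O,
    BVH-accelerated closest-point queries, rigid ICP registration, and a
    synthetic phantom generator with analytic ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
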