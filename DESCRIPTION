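Package: cystometer
Title: Automated Cyst Detection and Quantification in 3D Matrigel Brightfield Z-Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects and quantifies in vitro cysts grown in 3D Matrigel from
    brightfield focal-plane image stacks. Each plane is masked for artifacts,
    high-pass filtered with a discrete Laplacian, segmented with an adaptive
    local-mean threshold and refined by dilation, hole filling and erosion.
    Per-object size, centroid-to-boundary radius and eccentricity statistics
    feed rule-based exclusion of debris and artifacts; surviving objects are
    deduplicated across the z axis by footprint overlap and summarized as
    spherical cyst volumes per well and per treatment group. Also provides a
    synthetic phantom generator with known ground truth, miRNA seed-family
    aggregation statistics (cumulative fold change, miRNA-pool contribution,
    cross-model correlation), delta-delta-Ct polysome displacement, and
    ATP-linked oxygen consumption rate calculations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
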