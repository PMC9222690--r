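Package: sepso
Title: Optic Disc Segmentation by Subgroup-Partitioned Particle Swarm
    Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Segments the optic disc in retinal fundus region-of-interest
    images by evolving a closed contour with a subgroup-partitioned
    particle swarm (SePSO).  The search space is an annular polar
    exploration area around the disc centre, scored by the radial gradient
    of the red channel; each angular sector hosts one subgroup of
    particles and candidate boundaries ('Edges') are closed by taking one
    particle per subgroup, with an extra attraction term between adjacent
    subgroups.  Includes constant, linearly descending, random and
    chaotic-random inertia-weight schedules, periodic-spline and direct
    least-squares ellipse contour fitting, region-fraction evaluation
    metrics (accuracy, Dice, overlap error) with cumulative error
    reporting, a synthetic fundus generator with paired ground-truth
    masks, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
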