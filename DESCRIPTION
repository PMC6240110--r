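Package: rhogradients
Title: Modelling, Simulation and Quantification of Rho GTPase Activity
    Gradients at the Cell Front
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Steady-state activator/deactivator (GEF/GAP) models of the
    Cdc42 and Rac1 activity gradients found at the front of migrating
    cells, including the tip-localized GAP that bends the Rac1 gradient
    into a bump and the Cdc42/Rac1 crosstalk with in-silico knockdowns; a
    forward model of patterned optogenetic stimulation (gray-level light
    gradients on round micropatterns and the diffusion-limited membrane
    recruitment tail of CRY2/CIBN dimers); generators of synthetic FRET
    linescan ensembles, TIRF-like two-channel image stacks and migration
    movies with recorded ground truth; the image-to-profile
    quantification stage (ratio images, pre-stimulus subtraction,
    linescans, five-extreme normalization, decay-length/peak/extent
    metrics, pointwise rank-sum curve comparison, edge-enrichment
    fraction); and trajectory analysis (threshold segmentation, centroid
    tracking, windowed instantaneous speed, bootstrap angular precision,
    morphodynamic edge-velocity maps).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    minpack.lm,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
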