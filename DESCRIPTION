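Package: fishgrounds
Title: Weakly Supervised Fishing Ground Estimation from Sea Surface
    Temperature Rasters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates daily fishing grounds from gridded sea surface
    temperature (SST) by casting the task as keypoint detection with
    Gaussian heatmap regression. Catch logbooks give sparse but accurate
    ("strong") labels, while daily vessel trajectories give plentiful but
    noisy ("weak") labels; the package pre-trains a small convolutional
    heatmap regressor on trajectory-derived heatmaps with a per-sample
    confidence network that down-weights unreliable weak labels, then
    fine-tunes on catch-derived heatmaps. Includes an antimeridian-safe
    geographic raster frame, trajectory/catch annotation into three-channel
    heatmaps, geodesic precision/recall/F1 evaluation of detected peaks,
    and a fully synthetic ocean/vessel/catch simulator so the whole
    pipeline runs with no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
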