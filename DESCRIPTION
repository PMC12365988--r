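Package: DiskTilt
Title: Geometric Measurement of Flower-Head Inclination from Segmentation Masks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-contact measurement of sunflower flower-head (capitulum) tilt
    angle from instance-segmentation masks. Fits a general conic to the head
    boundary under the ellipse discriminant constraint and extracts the major
    axis, fits polynomial models to the stem centerline, intersects the stem
    curve with the head ellipse, and reports the angle between the major axis
    and the stem tangent at the intersection, in an oriented [0, 180) or an
    acute [0, 90] convention. Includes readers for raster masks and YOLO
    segmentation polygons, a seeded synthetic scene generator with known
    ground-truth angles, image augmentation utilities, dataset-split
    bookkeeping, and the evaluation statistics (RMSE, MAE, R-squared,
    angle-interval decomposition, error distribution summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    png,
    igraph,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
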