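Package: cartscan
Title: Articular Cartilage Thickness from Paired 3D Surface Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures articular cartilage thickness from paired 3D surface
    models of a bone scanned with and without its cartilage layer. Provides
    least-squares sphere fitting of fiducial markers, paired-point rigid
    registration (Kabsch/SVD) between the two scans, construction of the
    standard anatomical planes of the knee, extraction of distal (0 degree
    flexion) and posterior (90 degree flexion) condylar subregions, per-point
    closest-point thickness maps with summary statistics, mesh-deviation bias
    metrics (RMSD and average deviation), and two-scan precision propagation.
    Includes a synthetic phantom generator with machine-readable ground truth
    so every pipeline stage can be exercised without specimens.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
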