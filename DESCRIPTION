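Package: sphex
Title: 3D Reconstruction of Radially Symmetric Cells by Spherical Extrusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Reconstructs rod-shaped, radially symmetric cells (fission yeast
    and similar) in 3D from a single 2D midplane segmentation by extruding
    spheres along the topological skeleton, with radii taken from the
    Euclidean distance map. Includes brightfield whole-cell 2D segmentation
    from defocus boundary bands, per-section nuclear segmentation with
    Z-grouping into 3D nuclei, image calibration (dark noise, flat field,
    axial chromatic shift, axial distance correction), full morphometry
    (voxelized and idealized rod/ellipsoid volumes and surfaces, Feret and
    ellipse dimensions, fluorescence intensities, nuclear-to-cell volume
    ratio), and a synthetic phantom generator with analytic ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
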