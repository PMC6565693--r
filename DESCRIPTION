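Package: nctomo
Title: Nonrigid-Geometry Computed Tomography for Continuously Deforming Samples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Tomographic reconstruction of samples that deform continuously
  during acquisition. Straight parallel-beam lines of sight are replaced by
  curved virtual paths through a single reference volume, the curvature
  governed by a time-evolving deformation vector field (DVF) estimated
  jointly with the reconstruction from interleaved sub-tomogram
  acquisitions: 3-D optical flow between sub-tomogram and full
  reconstructions, Tikhonov temporal deconvolution onto interpolation
  nodes, projection-matching alignment, and nonrigid filtered back
  projection and SIRT solvers. Includes a numerical simulation study
  (porous pillar phantom deformed by a smooth random field) and quality
  metrics: Fourier shell correlation with the 1/2-bit threshold, DVF RMS
  error and principal components, and gray-level histogram bimodality.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: Rcpp, jsonlite, stats, tiff, utils, graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
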