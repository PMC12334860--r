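Package: clrt
Title: Treatment Planning for Converging-Lens Kilovoltage Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Inverse, non-coplanar treatment planning for converging-lens
    radiotherapy (CLRT), a kilovoltage modality in which an x-ray lens
    focuses a quasi-monoenergetic 60 keV hollow-cone beam onto a small
    focal volume. Provides a parametric dose kernel (anisotropic Gaussian
    focal volume plus attenuated convergent cone shell), water-equivalent
    radiological-depth ray tracing, planning-target sampling with
    depth-feasible beam-angle assignment, dose-influence-matrix assembly,
    bound-constrained beam-weight optimization with one-sided quadratic
    dose objectives, and plan evaluation (cumulative DVHs, conformity,
    coverage and gradient indices). Ships a synthetic phantom factory so
    the whole pipeline runs without clinical data, plus NRRD/NIfTI raster
    I/O and a thin command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    RNifti,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
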