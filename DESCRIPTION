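Package: fdot
Title: Frequency-Domain Diffuse Optical Tomography Forward Models and
    Anatomical Approximation-Error Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Forward modelling of frequency-domain diffuse optical
    tomography (FD-DOT) in segmented head models with two solvers: voxel
    Monte Carlo photon transport under the microscopic Beer-Lambert law
    with frequency-domain 'replay' absorption Jacobians, and the diffusion
    approximation discretized with first-order finite elements with
    adjoint-method Frechet sensitivities. Includes a harmonic level-set
    algorithm separating subarachnoid from sulcal/ventricular
    cerebrospinal fluid, landmark- and surface-based affine registration
    of head anatomies to a common exterior shell, a synthetic layered
    neonatal-head phantom generator with population variation, and
    approximation-error statistics (mean, covariance, eigenanalysis,
    visibility ratios and depth-sensitivity profiles) quantifying the
    effect of atlas-based anatomy on simulated measurements and
    sensitivity profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    RNifti,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
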