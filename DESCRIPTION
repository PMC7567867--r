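Package: densfunc
Title: Density-Based Kernel Learning of Coupled-Cluster Quality Energy Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Machine-learned density functionals for small molecules. A
    Gaussian approximation to the nuclear potential evaluated on a cubic
    grid is mapped by kernel ridge regression to electron-density
    expansion coefficients in an orthonormal Fourier basis (a learned
    Hohenberg-Kohn map), and a second kernel model maps those
    coefficients to molecular energies at a low (density-functional) or
    high (coupled-cluster) level of theory, or to the smooth difference
    between them (delta learning).  Includes point-group symmetry
    detection and training-set augmentation, Kabsch alignment, k-means
    training-point selection, finite-difference forces, NVE/Langevin and
    multiple-time-step (RESPA) molecular dynamics on the learned
    surfaces, geometry optimization, and a family of analytic surrogate
    molecular systems with two deterministic energy surfaces and
    analytic densities for end-to-end testing of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
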