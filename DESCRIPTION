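Package: slcTKD
Title: Sparse Low-Rank Tucker-2 Decomposition of Multi-Subject fMRI Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits a Tucker-2 tensor decomposition with an lp-norm
    (0 < p <= 1) spatial-sparsity constraint and Frobenius low-rank
    penalties to three-way (voxel x time x subject) fMRI tensors, using
    an alternating direction method of multipliers with half-quadratic
    splitting for the sparsity-constrained spatial factor. Recovers
    spatial maps and time courses shared across subjects together with a
    sparse core tensor, from which subject-specific intensities and
    spatial and temporal feature matrices are extracted and used to
    cluster subjects. Includes a synthetic multi-subject fMRI generator
    (sparse blob sources, haemodynamic block-design time courses,
    per-subject voxel dropout, SNR-controlled Gaussian noise) and
    correlation-based component-matching evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, graphics, utils, RNifti
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
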