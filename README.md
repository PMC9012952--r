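# slcTKD

Sparse low-rank Tucker-2 decomposition of multi-subject fMRI data.

Task fMRI experiments scanned across a group form a three-way tensor
**X** (voxels × time × subjects). Analysts want the spatial activation
maps (SMs) and time courses (TCs) that the group shares, plus a handle
on how strongly — and how differently — each subject expresses them.
`slcTKD` fits the Tucker-2 model

```
X = G ×₁ S ×₂ B + E        i.e. per subject  X_k = S G_k Bᵀ + E_k
```

with **S** (V × N) the shared spatial maps, **B** (T × N) the shared
time courses, **G** (N × N × K) a per-subject core tensor and **E** a
sparse residual. The fit is regularized the way fMRI signal behaves:
an ℓp quasi-norm (0 < p ≤ 1) on **S** (spatial activations are sparse),
Frobenius penalties on **S** and **B** (principal, low-rank factors),
and ℓ1 penalties on **G** (uniqueness) and **E** (robustness):

```
min ‖X − G ×₁ S ×₂ B − E‖²_F + μ_S‖S‖²_F + μ_B‖B‖²_F
    + δ‖S‖_p + λ‖G‖₁ + γ‖E‖₁
```

The optimizer is an ADMM with half-quadratic splitting for the
ℓp-constrained spatial factor, a per-subject discrete-time Sylvester
solve for the split core, soft-thresholding for the core and residual,
and geometrically growing penalties, started from a truncated
higher-order SVD. The core tensor is then mined for subject-level
information: mode-3 fibers give subject-specific intensities, and
spatial/temporal feature matrices (N × K) feed k-means clustering of
subjects into subgroups. A synthetic benchmark generator (sparse blob
sources, haemodynamic block-design TCs, per-subject voxel dropout,
SNR-controlled noise) and correlation-based evaluation utilities
complete the pipeline. See the methods vignette
(`vignettes/slctkd-methods.Rmd`) for the model, parameter and
numerical-design details.

## Worked example

```r
library(slcTKD)

sim <- simulate_fmri(fmri_sim_spec(grid = c(20, 20), n_sources = 4,
                                   n_timepoints = 60, n_subjects = 5,
                                   snr_db = 10, seed = 1))
fit <- slctkd(sim$X, order = 4, control = slctkd_control(iter_max = 80))
fit
#> Sparse low-rank Tucker-2 decomposition (slcTKD)
#>   data:  400 voxels x 60 time points x 5 subjects
#>   model order N = 4
#>   iterations: 53 (stopped on eps_min)
#>   final relative residual: 7.975e-08
```

The residual ε = ‖X − G ×₁ S ×₂ B − E‖_F/‖X‖_F reached 8·10⁻⁸, i.e.
the split model reproduces the data essentially exactly; iteration
stopped on the `eps_min` rule. Matching the estimated components to
the generator's ground truth by absolute Pearson correlation:

```r
m <- match_components(fit$S, fit$B, sim$truth$S_true, sim$truth$B_true)
m
#> component matching (greedy assignment)
#>   ref 1 -> est 1 (sign +1): |rho| SM 0.943, TC 0.980
#>   ref 2 -> est 2 (sign +1): |rho| SM 0.965, TC 0.983
#>   ref 3 -> est 3 (sign +1): |rho| SM 0.885, TC 0.833
#>   ref 4 -> est 4 (sign +1): |rho| SM 0.874, TC 0.911
```

Every planted source is identified (spatial |ρ| 0.87–0.97 at 10 dB
SNR), the task component (ref 1) best of all. Its per-subject
intensities — the mode-3 fiber of the core at the matched component
pair — recover the planted subject scalings:

```r
ci <- subject_intensities(fit$G, m$permutation[1], m$permutation[1],
                          normalize = TRUE)
round(ci, 3)
#> [1] 0.973 0.999 0.834 1.000 0.765
abs(cor(ci, sim$truth$subject_scales[, 1]))
#> [1] 0.996
```

`spatial_features()` / `temporal_features()` extract the N × K
subject-fingerprint matrices used by `cluster_subjects()`, and
`load_fmri_tensor()` / `write_map_nifti()` move between NIfTI volumes
and the masked-voxel tensor. A command-line wrapper over the same
functions is installed at `inst/cli/slctkd.R`.

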