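# stabdecode

Stability-aware model selection for sparse and structured-sparse brain
decoders.

## What problem this solves

Linear decoders classify brain scans by `sign(x'β)` with one coefficient
per voxel. Sparse penalties make the coefficient map look interpretable —
but sparse solutions can be *unstable*: hold out a different subject and
the selected voxels change substantially, which undermines any anatomical
interpretation. `stabdecode` makes that instability measurable and lets it
enter hyperparameter selection directly, for six penalized least-squares
decoders on masked 3D voxel grids:

| family | penalty Ω(β) |
|---|---|
| LASSO | λ₁‖β‖₁ |
| Elastic Net | λ₁‖β‖₁ + λ₂‖β‖₂² |
| TV | λ‖∇β‖₁ (anisotropic total variation) |
| sparse TV | λ(‖∇β‖₁ + ‖β‖₁) (3D fused lasso) |
| Laplacian | (λ/2)Σ_{i∼j}(βᵢ−βⱼ)² = λ β'Lβ |
| sparse Laplacian | λ(1−α)β'Lβ + λα‖β‖₁ (GraphNET) |

All are fitted by minimizing `(1/m)‖Xβ − Y‖² + Ω(β)` with a monotone
backtracking FISTA solver (exact soft-thresholding prox for ℓ₁, dual
projected-gradient prox for TV, their composition for sparse TV).

Model quality is assessed in nested leave-one-subject-out
cross-validation. Across folds the package computes, besides macro
(per-subject) accuracy:

* **sparsity** S(s) — fraction of nonzero coefficients after an
  ℓ₁-mass thresholding step;
* **overlap** O = |I∩I′|/max(|I|,|I′|) between supports;
* **corrected overlap** O꜀ = (|I∩I′| − E)/max(|I|,|I′|) with
  E = pSS′ the chance-level intersection — dense maps get zero;
* **correlation** — Pearson correlation of the raw coefficient maps.

Hyperparameters are then selected per external fold by one of three
criteria: best internal accuracy (**Acc**); smallest Euclidean distance to
the ideal point (1, 1) in the accuracy-vs-corrected-overlap diagram
(**Acc/OC**, sparse families only); or the same in the
accuracy-vs-correlation diagram (**Acc/Corr**).

The audience is methods-oriented neuroimagers and statisticians studying
decoder reproducibility; a synthetic block-design generator with planted
clustered signal makes every stage testable without any imaging data.

## Worked example

Simulate an 8-subject block-design experiment on a 10×10×10 grid with
three planted signal clusters, then compare accuracy-only selection with
accuracy + corrected-overlap selection for the LASSO (about a minute):

```r
library(stabdecode)

ph <- make_phantom(seed = 3)                  # 3 clusters, 99 signal voxels
d  <- simulate_dataset(ph, n_subjects = 8, n_per_class = 20, seed = 3)

grid <- default_hyper_grid(d, "lasso", n_lambda = 6, lambda_min_ratio = 1e-3)
res  <- nested_loso_run(d, grid, criteria = c("acc", "acc_oc"))
glance(res)[, c("criterion", "accuracy", "sparsity", "sparsity_sd",
                "overlap", "oc", "correlation")]
#>   criterion accuracy sparsity sparsity_sd overlap     oc correlation
#> 1       acc    0.912    0.681     0.17106   0.628 0.0428       0.889
#> 2    acc_oc    0.847    0.230     0.00605   0.614 0.3874       0.865
```

Reading the rows: selecting for accuracy alone classifies the held-out
subjects best (91.2%) but keeps two-thirds of the voxels, with
fold-to-fold sparsity swinging by ±0.17 and a chance-corrected support
overlap near zero (0.04). Adding stability to the criterion costs 6.5
accuracy points and returns maps that are three times sparser, almost
identically sized in every fold (SD 0.006), and far more reproducible
(O꜀ = 0.39).
`autoplot(res)` draws the internal accuracy-vs-stability diagrams these
selections were read from.

Ground truth lets us score support recovery directly. At high SNR a
sparse-TV fit finds the planted clusters with no false positives:

```r
d_hi <- simulate_dataset(ph, n_subjects = 4, n_per_class = 10, noise_sd = 0.2,
                         subject_sd = 0.2, signal = 0.5, seed = 3)
f <- fit_model(d_hi, penalty("stv", lambda = 0.05 * lambda_max_l1(d_hi)))
cluster_report(f)
#> # A tibble: 3 × 6
#>   cluster  size peak_x peak_y peak_z peak_value
#> 1       1    27      8      5      7  0.0403
#> 2       2    27      3      6      7 -0.0221
#> 3       3    26      4      4      9  0.0000860
recovery_scores(which(threshold_coefficients(f$beta) != 0), ph)
#>     tpr fpr    oc n_true n_est
#> 1 0.808   0 0.728     99    80
```

Real data enter through `read_dataset()` (NIfTI mask + scans, CSV labels
table with `volume`, `label`, `subject` columns); fitted maps leave
through `write_signature()` (NIfTI + JSON sidecar). A thin command-line
wrapper with `simulate` / `fit` / `select` / `report` subcommands is in
`inst/cli/stabdecode.R`.

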