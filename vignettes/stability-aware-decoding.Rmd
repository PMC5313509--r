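---
title: "Stability-aware model selection for sparse brain decoders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability-aware model selection for sparse brain decoders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(stabdecode)
```

## The problem

Multivariate decoders predict a mental state from a brain scan by a linear
rule $f(x) = \operatorname{sign}(x^\top\beta)$, with one coefficient per
voxel. With $p$ in the tens or hundreds of thousands and a few hundred
scans, the fit must be regularized, and sparse penalties are attractive
because a map with few active voxels looks interpretable. The catch is that
sparse solutions can be unstable: refitting after leaving out one subject
may select a very different set of voxels, which undermines any anatomical
reading of the map. This package implements a decoding framework in which
*stability across cross-validation folds is measured explicitly and can be
traded against accuracy during hyperparameter selection*.

## Models

All six decoders minimize
$$\frac{1}{m}\lVert X\beta - Y\rVert_2^2 + \Omega(\beta),$$
where $X \in \mathbb{R}^{m\times p}$ holds the masked scans as rows and
$Y \in \{-1,+1\}^m$ the condition labels. The penalties, expressed through
the discrete backward-difference gradient $\nabla$ and the grid-graph
Laplacian $L$ on the 6-neighbor graph of in-mask voxels:

| family | $\Omega(\beta)$ | character |
|---|---|---|
| LASSO | $\lambda_1\lVert\beta\rVert_1$ | sparse, unstructured |
| ENET | $\lambda_1\lVert\beta\rVert_1 + \lambda_2\lVert\beta\rVert_2^2$ | sparse, correlated voxels kept together |
| TV | $\lambda\lVert\nabla\beta\rVert_1$ | piecewise constant, dense |
| STV | $\lambda(\lVert\nabla\beta\rVert_1 + \lVert\beta\rVert_1)$ | sparse and piecewise constant (3D fused lasso) |
| LAP | $\tfrac{\lambda}{2}\sum_{i\sim j}(\beta_i-\beta_j)^2$ | smooth, dense |
| SLAP | $\tfrac{\lambda(1-\alpha)}{2}\sum_{i\sim j}(\beta_i-\beta_j)^2 + \lambda\alpha\lVert\beta\rVert_1$ | sparse and smooth (GraphNET) |

Two conventions are worth stating because the literature is loose about
them. First, the neighbor sum $\sum_{i\sim j}$ runs over *ordered* pairs,
so that its half equals the Laplacian quadratic form
$\beta^\top L\beta$ exactly; this keeps the LAP/SLAP penalty equal to
$\lambda\,\beta^\top L\beta$ and makes `penalty_value()` and the solver's
gradient consistent by construction. Second, the TV norm is the
*anisotropic* $\ell_1$ norm over all $3p$ gradient components, matching the
backward-difference definition componentwise (not the isotropic per-voxel
$\ell_2$ variant). Voxels outside the mask behave exactly like the grid
boundary: no difference is taken across them and they contribute no graph
edge, which is the only reading consistent with penalizing after gray-matter
masking.

There is no intercept: classes are balanced by design and the decision
rule is a pure sign. `sign(0)` maps to $+1$, a documented convention so
predictions are always in $\{-1,+1\}$. Feature centering exists as an
explicit, off-by-default option.

## Solver

`fit_model()` runs a monotone accelerated proximal gradient method
(FISTA). The smooth part collects the data term plus the quadratic
penalties ($\lambda_2\lVert\beta\rVert^2_2$ and the Laplacian form); the
nonsmooth part collects $\ell_1$ and TV, handled by proximal maps:

* $\ell_1$: exact soft-thresholding;
* TV: solved on the dual ball by accelerated projected gradient with
  adaptive restart (inner tolerance $10^{-8}$ on the max-norm dual change,
  500 inner iterations by default, warm-started within a fit), returning
  the best iterate with a warning if starved;
* STV: soft-thresholding composed after the TV prox. This composition is
  the exact prox of the sum (the fused-lasso composition identity); the
  test suite validates it against an exact taut-string solver on 1D masks
  and a brute-force oracle on small 3D instances rather than assuming it.

Steps use backtracking from a power-iteration Lipschitz estimate, each
accepted step satisfying the standard quadratic upper bound, and a
monotone (MFISTA-style) acceptance rule so the objective trace never
increases; momentum restarts after an overshoot. The solver stops when the
relative objective change stays below `tol` ($10^{-6}$ by default) for
three consecutive accepted iterations, or at `max_iter` (5000).

Every fit starts from $\beta = 0$. This matters more than it may look:
with $m < p$ and weak regularization the minimizer need not be unique, and
warm-starting fits from neighboring hyperparameters or folds would couple
the returned solutions, quietly inflating the very stability measures the
framework is supposed to estimate. Zero initialization makes each
signature a deterministic function of its training data alone. The
validation suite checks the solver against an independent
proximal-subgradient reference optimizer, closed forms (ridge normal
equations, soft-thresholding), glmnet on LASSO/ENET instances, and the
degenerate-family identities SLAP($\alpha{=}0$) $\equiv$ LAP and
ENET($\lambda_2{=}0$) $\equiv$ LASSO.

## Thresholding, stability metrics, accuracy

Optimization leaves tiny nonzeros where exact zeros belong, so supports
are read off after `threshold_coefficients()`: order the magnitudes
decreasingly and keep the minimal prefix carrying at least
$(1-10^{-4})$ of the $\ell_1$ mass. Ties break by index; the output is
deterministic. Thresholding is applied to every fitted coefficient vector
before support-based measures, in both the internal and external loops.

For signatures $\beta(s)$ (subject $s$ held out) with supports $I_s$:

* overlap $O_{s,s'} = |I_s\cap I_{s'}| / \max(|I_s|,|I_{s'}|)$;
* corrected overlap subtracts the chance-level expected intersection
  $E = pS(s)S(s') = |I_s||I_{s'}|/p$ of two random supports of the same
  sizes before normalizing — a dense model overlaps with itself entirely
  but gets corrected overlap $0$, which is the point of the correction
  (slightly negative values are possible and are used raw);
* correlation is the Pearson correlation over *all* $p$ coefficients of
  the raw (unthresholded) vectors, zeros included.

Means are taken over the $N(N-1)$ ordered off-diagonal pairs. When both
supports are empty the overlap measures are defined as $0$ with a warning:
an empty model carries no reproducible pattern. Accuracy is macro-averaged
— fraction correct per subject, then the unweighted mean over subjects —
never pooled over scans, so a subject with many scans cannot dominate.

## Nested leave-one-subject-out selection

All scans of one subject leave together (this is not leave-one-example-out).
The external loop measures; the internal loop selects. For each external
fold, every hyperparameter combination is fitted on each internal fold and
summarized as a point (mean internal accuracy, mean internal stability).
Three criteria read this diagram:

* **Acc** — maximize mean internal accuracy;
* **Acc/OC** — minimize the Euclidean distance to the ideal point $(1,1)$
  in the accuracy vs corrected-overlap diagram (sparse families only;
  requesting it for TV or LAP is an error);
* **Acc/Corr** — the same distance in the accuracy vs correlation diagram.

Accuracy enters the distance on its natural $[0,1]$ scale. Stability alone
is deliberately not offered as a criterion: a constant one-voxel model
would be perfectly stable and useless. Ties break toward stronger
regularization (larger $\lambda$, then larger $\lambda_1$/$\alpha$).
Internal accuracy applies the macro average over the internal left-out
subjects, i.e. the same estimator as the external loop, rather than
averaging fold accuracies of unequal meaning.

Default grids are log-spaced over
$[10^{-4}\lambda_{\max},\ \lambda_{\max}]$ with
$\lambda_{\max} = 2\lVert X^\top Y\rVert_\infty/m$, the smallest $\ell_1$
weight that zeroes the LASSO solution — a natural common scale since all
families compete against the same loss; ENET crosses this with a 5-point
$\lambda_2$ grid and SLAP with $\alpha\in\{0.1,0.25,0.5,0.75,0.9\}$.

One exact computational identity is worth noting: the internal training
set of external fold $i$, internal fold $j$ excludes precisely subjects
$\{i,j\}$ — the same set as external $j$, internal $i$. `nested_loso_run()`
therefore fits each unordered subject pair once and reuses the fits,
halving the internal work without changing any number; a test asserts the
reuse reproduces the direct computation. No-leakage is likewise asserted
by a canary test: corrupting every scan and label of the held-out subject
changes nothing in that fold's fitted signature.

## The synthetic testbed

The generator produces the statistical skeleton of a multi-subject
block-design experiment on a desk-scale grid:
$$x_i = y_i\,a\,w^\star + \text{smooth}(\varepsilon_i) + b_s,$$
with $w^\star$ a phantom of a few face-connected clusters with alternating
signs (constant profile for the TV/STV regime, Gaussian bumps for
LAP/SLAP), $\varepsilon_i$ white noise smoothed by a separable Gaussian,
and $b_s$ a smoothed subject-specific offset field shared by all scans of
subject $s$. The mean-shift construction makes $\beta \propto w^\star$
Bayes-optimal under isotropic noise, the cleanest possible ground truth
for support recovery.

Parameter choices, made once:

* **Grid and design**: benchmark runs use $10\times10\times10$
  ($p = 1000$), 8 subjects, 20 scans per class per subject, replicated
  over ten seeds — the largest size at which a full nested LOSO study
  over two families and replicate seeds remains a desk-scale computation
  (a single nested run fits roughly a thousand models). The generator
  default of 42 scans per class matches a typical per-condition count in
  a block design; an ellipsoidal mask option exercises masked-boundary
  code paths.
* **Smoothing width 1 voxel (SD)**: acquisition pipelines smooth with
  $\approx 8$ mm FWHM at 3 mm voxels, i.e. an SD near 1.1 voxels; 1 voxel
  at phantom scale reproduces that degree of local noise correlation.
* **Subject offset SD equal to scan-noise SD (both 1)**: between-subject
  variability is a first-order obstacle to leave-one-subject-out
  generalization in practice, so it is not made negligible.
* **Signal amplitude 0.0125**: calibrated, before any selection-criterion
  experiment was run, so that well-regularized decoders reach held-out
  accuracies in the mid-80s to low-90s percent with an interior optimum
  along the regularization path — the regime of single-scan affective
  decoding. Stronger signal saturates accuracy at 1 and makes every
  criterion trivially agree; weaker signal pushes everything to chance.
* **Benchmark grid**: 6 log-spaced $\lambda$ values over
  $[10^{-3}\lambda_{\max},\ \lambda_{\max}]$, instead of the 15-point
  $10^{-4}$ default used for ordinary selection runs. The nearly
  unregularized tail of the path costs the large majority of solver
  iterations in every internal fold while the criteria comparison reads
  the same internal fits either way; the shallower grid keeps the
  replicated two-family benchmark inside a desk-scale compute envelope.

What the generator does *not* model: hemodynamic response shape,
scan-to-scan temporal autocorrelation, motion artifacts, physiological
noise, or subject-specific displacement of the informative clusters.
Passing benchmarks therefore demonstrate that the machinery measures and
trades off what it claims on data with realistic second-order spatial
structure — not that any method will behave identically on real fMRI.

One empirical regime observation, visible in the benchmark itself: because
the noise is spatially smooth, it is cheap under the TV seminorm, so at
moderate $\lambda$ the TV-bearing families can fit smooth noise while
looking regularized; at desk scale STV's accuracy-stability diagram is
consequently much flatter than LASSO's, and distance-based selection for
STV can land on strongly regularized, stable but inaccurate models. This
is a property of the simulated regime worth keeping in mind when reading
benchmark numbers across families.

## Numerical conventions and degenerate inputs

* `sign(0)` predicts $+1$; labels accept $-1/1$, $0/1$ or two-level
  factors.
* Both-empty supports give overlap and corrected overlap $0$ with a
  warning; constant vectors give correlation $0$ with a warning.
* The thresholding fraction must lie in $[0,1)$; $\beta = 0$ thresholds
  to itself.
* Failed fits inside the internal loop flag their grid point, which is
  excluded from selection; failures of a chosen refit abort the run with
  a diagnostic.
* All randomness (phantom placement, simulation noise) flows from
  explicit integer seeds; fitting itself is deterministic, so identical
  inputs give bitwise-identical results.
* The spectral bound for the step size, like the Gram blocks, is computed
  per fold from that fold's training rows only, so held-out scans cannot
  influence a fit even through the step size; backtracking absorbs any
  slack in the power-iteration estimate.

## Limitations

The solver targets desk-to-moderate problem sizes (the Gram-path and the
matrix-free path switch automatically); at $p \sim 10^5$ real-data scale a
fit is minutes, not seconds. The TV prox is iterative, so TV-family
solutions are exact only to the configured inner tolerance — the
thresholding step exists precisely to absorb that. Only the square loss is
implemented (logistic and hinge variants would change none of the
selection machinery but are out of scope), classification is binary, and
isotropic TV is deliberately not offered.
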