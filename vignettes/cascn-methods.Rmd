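---
title: "Models and methods: morphometric networks for tremor phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: morphometric networks for tremor phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the statistics it implements:
the models and their assumptions, the tunable parameters and their
defaults, what the synthetic generator emulates, the numerical choices, and
the places where the design was genuinely open and we had to decide.
It states no empirical result that the test suite does not itself compute.

## 1. The analysis problem

Tremor-dominant Parkinson's disease (TD) and essential tremor (ET) are
clinically hard to separate, but their structural brain changes differ: TD
cohorts show pallidum enlargement and precuneus-centred cortical change, ET
cohorts thalamic volume loss and prefrontal/occipital change. The package
implements a complete analysis chain over subject-level morphometry —
vertex-wise cortical thickness (mm) and subcortical volumes (mm³) for three
groups (TD / ET / healthy controls, HC) — ending in a directed
"progression" network per disease and a TD-vs-ET classifier.

## 2. Vertex-wise GLM and cluster-level inference

At each vertex we fit an ordinary least squares model
`thickness = Xb + e` with intercept, a group indicator and covariates
(age, sex by default), and test a contrast with a two-sided t statistic on
`n - rank(X)` degrees of freedom. Vertices with `p < 0.01`
(cluster-forming threshold) are grouped into connected components under the
atlas adjacency, split by sign so each cluster is a pure "increase" or
"decrease".

Two corrections for the cluster search are provided:

* **Monte-Carlo simulation (MCS)** — the null distribution of the maximum
  cluster size is built from synthesised Gaussian fields smoothed to the
  smoothness estimated from the data, and each observed cluster receives
  `corrected_p = (1 + #{null max >= size}) / (n_iter + 1)`. The add-one
  convention avoids zero p-values; `n_iter < 100` is rejected because the
  tail becomes unstable. A group-label permutation variant
  (`cluster_correct_permutation`) provides an assumption-light cross-check.
* **Gaussian random field (GRF) theory** — for a 2-D field with `R =
  V / FWHM^2` resels and threshold `u` (z scale), the expected cluster
  count per sign is `E[m] = R (4 log 2) (2*pi)^{-3/2} u exp(-u^2/2)`, the
  expected supra-threshold count `E[N] = V * Phi(-u)`, cluster extent is
  approximately exponential in two dimensions (`P(n >= k) =
  exp(-k E[m]/E[N])`), and the familywise p of a size-`k` cluster is
  `1 - exp(-2 E[m] P(n >= k))`. The approximation degrades at lenient
  thresholds, so `cluster_forming_p >= 0.05` warns.

Field smoothness is estimated from the variance of nearest-neighbour
differences over the mesh edges (the Forman/AFNI estimator adapted to graph
adjacency): `var(x_i - x_j) / (2 var x) = 1 - exp(-1/(4 sigma^2))` for a
Gaussian-autocorrelation field, inverted for sigma and reported as FWHM in
vertex units. Estimates below one vertex spacing are floored at 1 — the
lattice cannot witness smaller smoothness, and white noise therefore
reports FWHM 1. The acceptance suite verifies that both corrections hold
their familywise error on 200 null cohorts (MCS within [0.03, 0.08], GRF at
or below 0.08, nominal 0.05).

Subcortical volumes use per-structure ANCOVA (group F test adjusting age +
sex), Benjamini-Hochberg FDR across structures, and Bonferroni-adjusted
(`min(1, 3p)`) pairwise contrasts for structures passing FDR < 0.05. The
covariate set of the original analysis is not printed anywhere we could
verify, and its F values are not recomputable from summary statistics
alone; age + sex is therefore a documented default, with estimated total
intracranial volume accepted as an extra column when present.

## 3. Seed-based structural covariance (SCN)

Structural covariance asks whether the thickness of a seed region co-varies
across subjects with the thickness elsewhere, and whether that coupling
differs between a patient group and HC. Two formulations exist in the
literature: comparing per-group correlations (Fisher z), and a single
interaction GLM. We default to the GLM because it admits covariates in the
same breath:

`thickness_v = b0 + b1*seed + b2*group + b3*(seed x group) + covariates`

with patients coded 1, so `b3 < 0` reads "covariance decreased in
patients". The Fisher-z route is exposed as `scn_correlation_diff` for
cross-checking. The seed's own vertices are excluded from the target set
(t = 0, p = 1); including them would only report the seed's perfect
covariance with itself. Swapping the group coding negates the interaction
map exactly — a property the unit tests assert.

## 4. Causal structural covariance networks (CaSCN)

Cross-sectional data cannot reveal temporal dynamics directly. CaSCN
substitutes disease duration for time: patients are sorted by duration
(ties broken by subject id, a stable deterministic rule), and the resulting
"pseudo-time series" of regional thickness is treated as a sequence. For a
source series `x` and target `y` the package fits

`y_t = a + b*y_{t-1} + c*x_{t-1}`

and reports the signed path coefficient `c`. The model order is fixed at 1:
pseudo-time has no sampling interval, and with ~70 points higher orders
overfit. Only positive coefficients are interpreted (a region "driving"
change elsewhere); vertex-wise maps z-score the retained coefficients and
calibrate them by permuting the subject ordering with max-statistic
familywise control, keeping clusters strictly larger than 10 vertices.
Because no correction method is named for this stage in the source
analysis, permutation of the duration ordering was chosen: it is valid
under exchangeability and agnostic to the statistic.

Series are standardised (mean 0, SD 1) before the autoregressive fits in
the map and matrix operations. The raw coefficient of `y` on `x` scales
with `sd(y)/sd(x)`, so without standardisation the comparison between a
pair's two directions would be driven by deviation amplitudes rather than
temporal structure; `signed_path_gca` itself operates on raw series so it
can be checked against the closed-form normal-equations oracle.

**Binarisation.** The ROI-to-ROI matrix is thresholded into a directed
graph two ways: `mode = "z"` keeps entries at least `z_threshold` (default
1) above the off-diagonal mean, and `mode = "significance"` keeps entries
whose GC t-test p is below 0.05 — the reading most parallel to the
vertex-wise stage, which also gates on significance. In both modes,
reciprocal pairs are pruned to their dominant direction by default
(`dominant_only = TRUE`). This net-causality rule is load-bearing: on a
duration-ordered pseudo-time series both directions of a genuinely lagged
influence are strong shape predictors (the latent duration drives both
series deterministically), so the reverse edge routinely clears any fixed
threshold; the directional signal lives in the forward-minus-reverse
contrast. Without the rule, the package's own planted-source recovery
experiment fails at any threshold — a limitation of bivariate
pseudo-time Granger analysis worth knowing about before interpreting
published CaSCN hubs.

Binary out-degree (row sums of the adjacency, diagonal excluded) ranks
regions as progression sources; in-degree ranks sinks.

## 5. The synthetic cohort generator

`cohort_spec()` states the world the tests live in:

| parameter | default | why |
|---|---|---|
| group sizes | 69 / 71 / 80 | the published cohort |
| duration (y) | TD 9.28 ± 7.16, ET 16.41 ± 12.48, truncated at 0 | published; ties kept to exercise the tie rule |
| baseline thickness | 2.5 mm | typical cortical mean |
| noise SD | 0.25 mm | typical between-subject vertex SD |
| smoothing FWHM | 3 vertices | exercises cluster topology without huge meshes |
| subcortical baselines/SDs | published HC means/SDs | Pallidum.L/R, Thalamus.L/R |
| subcortical shifts | published TD-HC and ET-HC differences | pallidum up in TD, thalamus down in ET |
| clinical scores | published patient means/SDs; HC explicit NA | drives Table-1-style tests |
| H-Y stages (TD) | P(stage 1..4) = .09/.20/.40/.31 | ~29% early (stage <= 2), matching the published early-TD fraction |

The mesh is a 2-D grid, not a sphere: every inference in the package
depends on adjacency and smoothness, not on embedding, and a grid
exercises identical topology with far simpler code. Smooth noise is white
noise convolved with a separable Gaussian kernel on a padded grid, cropped
and rescaled so the marginal SD is exact at every vertex.

Cascade effects operationalise progression: an edge plants
`rate * min(d, saturation)` mm at its source and
`rate * min(max(d - lag, 0), saturation)` at its target for a patient with
duration `d`. The saturating ramp (rather than unbounded linear growth)
keeps late-duration subjects from dominating the autoregression. No
cortical effect sizes are published for these cohorts — only significance —
so cascade magnitudes are chosen for testability, not fidelity.

**The source-recovery fixture** (`source_recovery_spec()`) deserves its own
caveat. It plants one source region driving five targets at a 5-year lag
in 70 ET-like patients and asks the CaSCN chain to hand the source the
strictly maximal out-degree. Exploration during development showed that
bivariate pseudo-time GC direction detection degrades quickly with
measurement noise (the two directions of each pair converge), that targets
sharing a lag are mutually exchangeable, and that a node's distant-lag
edges lose significance. The fixture therefore uses a near-noiseless
regime (`noise_sd` 0.02 mm, region-mean noise ≈ 0.002 mm) and
significance-mode thresholding. A green recovery test certifies the
machinery — ordering, fitting, z-scoring, pruning, degree logic — under
favourable conditions; it does not certify that real cohorts at realistic
noise yield trustworthy source attributions. The remaining failures in the
fixture are cohorts whose duration draw contains almost no patients below
the 5-year onset, leaving the lag unidentified — an honest reminder that
the method needs coverage of the onset window.

## 6. Classification protocol

Stratified 3:1 split (class proportions preserved within one subject);
LASSO stability selection — each repeat re-draws 10 folds, `cv.glmnet`
picks the penalty by deviance, and nonzero-coefficient features are
counted; features selected in strictly more than `threshold` of
`n_repeats` survive. The source protocol states both ">500 of 1000"
(methods) and "top 30%" (results); both modes are implemented and
`count_threshold` is the default, the methods text being the more precise
statement.

No SVM or random-forest library is available in the target environment, so
the five learners are in-package: a CART-style random forest (Gini splits,
per-node feature subsampling, 500 trees by default) and L2-regularised
kernel logistic regression with the four classic SVM kernels, solved by
Newton-IRLS in the dual with a constant-kernel intercept. The kernel
machines keep the `SVM-*` names of the protocol and emit calibrated
probabilities directly, which is what the AUC evaluation consumes; hinge
losses would need an extra Platt-scaling step to say the same thing.
Features are z-standardised on the training split for the penalised and
kernel models; the forest consumes raw features. Hyperparameter grids are
small and printed in the tuned bundle: cost over four decades
(`10^-1 .. 10^2`), forest `mtry` over `{sqrt(p), p/2}`.

Evaluation bootstraps the test subjects (resamples with a single class are
redrawn, capped at 10x) and reports the AUC sample, mean and percentile
interval per learner. "1000 resamples" could also mean repeated splits;
bootstrap-of-test-subjects is the implemented reading because it leaves the
training fixed, matching "retested on 1000 resamples".

## 7. Numerical and degenerate-input choices

- p-values are clamped into `(0, 1]`; corrected permutation p uses the
  `(1+x)/(1+n)` convention, so 0 is unreachable.
- Rank-deficient designs fail fast, naming the collinear columns from the
  pivoted QR.
- Constant series, constant seeds within a group, self-causality
  (`x ≡ y`), HC pseudo-time requests, duplicate ROI names, unknown regions
  and structures are all hard errors with specific messages; an all-negative
  GC map is a warning plus an empty result, because it is a legitimate
  outcome.
- All table and network writers emit 17 significant digits; write-then-read
  is bit-lossless (GraphML is written by hand for this reason).
- Every stochastic operation takes a `seed` argument applied via a scoped
  RNG so the caller's random state is never disturbed; the pipeline derives
  one seed per stage from a single master seed, all below 2^31.

## 8. Known limitations

- The atlas is an abstract labelled graph; no surface geometry, NIfTI/GIFTI
  I/O, or genuine FreeSurfer metadata beyond the `ColHeaders` table.
- GRF constants are the classic 2-D expected-cluster formulation; at very
  low smoothness or lenient thresholds it is only approximate (the MCS and
  permutation routes are the fallback).
- Bivariate (not conditional) Granger causality only, by design; directed
  edges can reflect shared upstream drivers.
- The generator does not model scanner effects, site structure, cortical
  geometry, or realistic effect sizes for cortical clusters; green tests
  certify machinery and calibration, not clinical effect detectability.
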