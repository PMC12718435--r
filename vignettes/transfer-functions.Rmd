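---
title: "Diatom-environment calibration: models, screening and diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diatom-environment calibration: models, screening and diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(diatomtf)
```

`diatomtf` builds temperature (or any single-variable) transfer functions
from coastal diatom training sets: paired surface-sediment assemblages and
water-column measurements along a gradient. The package covers the whole
chain — preprocessing, environmental-variable screening, calibration,
cross-validation and spatial diagnostics — and ships a seeded synthetic
generator with known taxon responses so every estimator can be checked
against ground truth. This vignette explains the models, the defaults and
the judgement calls.

## The calibration model

Let $y_{ik}$ be the abundance of taxon $k$ at site $i$ and $x_i$ the
environmental value (here temperature in °C). Weighted averaging (WA)
estimates each taxon's **optimum** and **tolerance** as the
abundance-weighted mean and SD of the gradient:

$$\hat u_k = \frac{\sum_i y_{ik} x_i}{\sum_i y_{ik}}, \qquad
  \hat t_k = \sqrt{\frac{\sum_i y_{ik} (x_i - \hat u_k)^2}{\sum_i y_{ik}}},$$

with Hill's $N_2 = (\sum_i y_{ik})^2 / \sum_i y_{ik}^2$ recording how many
sites effectively support the estimate (`estimate_responses()`). A site's
initial inference is the abundance-weighted mean of the optima of the taxa
present; taking means twice compresses the range, so a linear *deshrinking*
follows: **inverse** regresses observations on estimates, **classical**
regresses estimates on observations and inverts the line (`fit_wa()`).
Optional tolerance down-weighting multiplies each taxon's weight by
$1/\hat t_k^{*2}$ so narrow-niche taxa count more.

**WAPLS** (`fit_wapls()`) generalizes this: each component starts as the WA
optima of the running residual of $x$, site scores are weighted averages of
those taxon scores, each new component is orthogonalized against its
predecessors and standardized, and $x$ is regressed on all components to
date. Extra components can exploit structure in the assemblage that plain
WA ignores, at the price of more variance.

### Numerical choices in the engines

* **Equal site weights everywhere.** The deshrinking regressions and the
  WAPLS component regressions/orthogonalizations use equal site weights
  (ordinary least squares). On row-normalized (proportion) input — the
  pipeline's canonical case — this coincides with weighting sites by their
  assemblage totals, and it makes a clean identity hold *exactly* on any
  input: WAPLS with one component and inverse-deshrunk WA produce the same
  predictions (asserted to 1e-8 in the tests). That identity is the standard
  sanity anchor between the two engines, and preserving it on arbitrary
  matrices was judged more valuable than total-weighted regression on
  non-normalized input, where the two conventions diverge.
* **Component scaling.** Each WAPLS component is centred and scaled to unit
  (population) variance before regression; predictions are invariant to this
  choice, it only conditions the arithmetic. The orthogonalization
  coefficients are folded back into the stored taxon scores, so a fitted
  model predicts new assemblages with one matrix product.
* **Tolerance floor.** Tolerance down-weighting uses
  $\hat t^*_k = \max(\hat t_k,\ 0.01 \times \text{gradient span})$, and taxa
  with a single occurrence (whose tolerance is identically 0) get the mean
  finite tolerance instead. Without the floor, single-site taxa would carry
  infinite weight.
* **Degenerate inputs.** A constant target gives a zero-component WAPLS
  model that predicts the constant; requesting more components than the
  matrix supports fails with the maximum usable count; an assemblage with no
  training taxa gets a flagged `NA` prediction plus a `coverage` statistic
  (fraction of valves belonging to training taxa), never a silent number.

## Preprocessing

Counts become proportions per site (`relative_abundance()`); the rare-taxon
rule keeps taxa reaching at least 1 % relative abundance in at least two
sites (`rare_taxon_filter()`, both thresholds exposed — a stricter
">2 % in one site" variant used for display purposes elsewhere is a
parameter choice away). Proportions are *not* renormalized after filtering,
so row sums still report the share of counted valves retained;
`renormalize = TRUE` is available. The Hellinger transform
(`hellinger()`) — square roots of row-normalized proportions — makes
Euclidean geometry, and hence linear ordination, appropriate for community
data. Environmental variables whose adjusted Fisher–Pearson skewness
(type 2, the common sample-adjusted form) exceeds 1 in absolute value are
log10(x+1)-transformed, then everything is centred and scaled
(`transform_env()`); the threshold is configurable because "if necessary"
is a judgement, not a number.

## Variable screening

With ~20 collinear water-column variables and ~35 sites, screening comes
before calibration:

1. **Correlation groups** (`correlation_groups()`): variables linked when
   $|r| > 0.8$ with $p < 0.001$ (t distribution on $n-2$ df, the usual
   Pearson test; the source procedure names the thresholds but not the
   p-value machinery); groups are connected components, so one
   representative per group suffices.
2. **Gradient length** (`dca_gradient_length()`): detrended correspondence
   analysis, 26 detrending segments and nonlinear rescaling by default (both
   configurable), returns the first-axis length in species-turnover SD
   units; below 2 SD species responses are close to linear over the gradient
   and RDA is the right constrained method. Short coastal temperature
   gradients sit firmly in this regime.
3. **RDA and partial RDA** (`rda_fit()`): principal components of the
   fitted values of the multivariate regression of (Hellinger-transformed,
   centred) species data on the constraints, residualized on any covariates
   first. Implemented in-package via QR/SVD so that partialling, the fast
   permutation path and score conventions stay under package control; the
   tests pin it against both a brute-force projection oracle and vegan.
4. **Permutation tests** (`permutation_test()`): pseudo-F with free
   (unrestricted) permutation of the constraint rows while covariates stay
   fixed, and $p = (1 + \#\{F^* \ge F\})/(1 + n_{\text{perm}})$; 999
   permutations by default. Reduced-model residual permutation is a
   plausible alternative; free permutation matches the stated procedure.
5. **Forward selection** (`forward_select()`): the candidate adding the most
   variance among those with conditional $p \le \alpha$ joins the model;
   ties break lexicographically for reproducibility. The permutation floor
   $1/(n_{\text{perm}}+1)$ must be at or below $\alpha$, or nothing can ever
   be selected — the pipeline configuration warns about that combination.
6. **Independence tests** (`independence_test()`): each member of a selected
   pair is re-tested with the other as covariate; losing significance means
   "dependent", and the variable with the larger marginal variance is
   retained.
7. **λ₁/λ₂** (`lambda_ratio()`): the variance on the single constrained axis
   over the first residual axis of the same partial model; above 0.5 the
   variable structures the assemblage strongly enough to calibrate against.
   The wording "second non-constrained axis" in common usage is resolved by
   the arithmetic of published screening tables: the printed ratios equal
   RDA1 % ÷ PC1 %, i.e. the *first* residual axis, and that is what the
   package computes.
8. **Variance partition** (`variance_partition()`): per-variable partial
   RDAs, by default conditioning each variable on all other selected
   variables plus the covariates (conditioning on covariates alone is the
   other supported convention, since published tables rarely say which was
   used). Percentages are on the total-variance scale so the joint,
   covariate and total explained shares add up the way screening tables
   report them.

## Validation

`loo_predictions()` refits the *entire* model — response estimation,
deshrinking, WAPLS chain — without each site in turn (the jackknife);
`performance_stats()` reports RMSE(P), $r^2$ (squared Pearson correlation,
the convention here; $1 - SSE/SST$ differs under bias and is documented as
such), average bias, and maximum bias: the largest absolute mean residual
over 10 equal-width gradient segments (the count is configurable; 10 is the
convention of the standard calibration software). `model_selection_table()`
crosses the seven standard engines {WA inverse/classical, both with
tolerance down-weighting, WAPLS 1–3} with {Hellinger, untransformed} and
marks the winner by the documented lexicographic rule — highest cross-
validated $r^2$, then lowest RMSEP, then lowest maximum bias. The full grid
is always emitted: published studies sometimes prefer a model that does not
win every column, and that choice belongs to the analyst, not the software.
`outlier_screen()` flags sites whose absolute LOO residual exceeds 2.5
residual SDs and reports before/after performance; removal itself is a
config decision (`exclude_sites`), never automatic.

### Spatial autocorrelation (RNE)

Cross-validated skill is inflated when training sites near the test site
duplicate its assemblage for reasons other than the calibrated variable.
`rne_analysis()` compares three deletion schemes during leave-one-out: all
training sites within a geographic radius of the test site (*neighbour*),
the same number closest in the target variable (*environment*), and the
same number at random (10 repetitions by default; matching the deletion
counts keeps the three schemes comparable). A neighbour curve dropping well
below the random curve is the signature of spatially inflated skill. The
default radius grid {0, 1, 2, 5, 10, 20, 40} km spans the sub-spacing to
half-transect range of an ~80 km coastal transect; radius 0 reproduces
plain leave-one-out exactly. Folds that lose their entire training set, or
too much rank for the requested WAPLS components, are flagged and excluded
rather than aborting the curve.

## Community description

`cluster_sites()` (Euclidean + Ward by default — on Hellinger assemblages
that is the Hellinger distance, the same geometry the ordination uses)
returns the tree, a k-cut, silhouette summary and a newick export.
`indval()` computes indicator values per taxon and site group: specificity
$A$ (share of the taxon's across-group mean abundance in the group),
fidelity $B$ (fraction of the group's sites occupied),
$\text{stat} = \sqrt{AB}$, with label-permutation p values; group
combinations are supported but off by default. For indicator analysis
against a continuous gradient the default grouping is 1 °C bins
(`gradient_classes()`), since "indicators of temperature between 12 and
13 °C" is the granularity such analyses are reported at.

## The synthetic generator

`sim_config()` + `make_benchmark()` emulate the structure of a subarctic
coastal training set: 35 sites along an 80 km transect, a short temperature
gradient (10.3–13 °C) from a smooth spatial field (exponential covariance,
10 km correlation length) plus a contiguous warm bay block; Secchi depth as
a strong negative affine of temperature; turbidity and Mn completing a
"physical" correlated block; salinity/TDS/conductivity on one latent
factor; Cl, Na, K, SO₄, Mg on a river-diluted ion factor with dissolved
silica mirroring it negatively (river mouths are silica-rich, ion-poor);
and 55 benthic + 19 planktonic taxa with Gaussian (unimodal) responses,
evenly spread optima, and multinomial counts of 400–500 valves per site.
The Gaussian-response/multinomial pair is the canonical generative model
under which WA-type calibration is consistent, which is what makes
parameter recovery on these data a meaningful check rather than a tautology.

Parameters worth knowing, with defaults and reasons:

* `noise_sd` (0.25 °C): site-level noise on the gradient the assemblages
  actually respond to — unmeasured variables, in model form.
* `spatial_range` (10 km): correlation length of every spatial field;
  0 gives iid fields.
* `bay_amplitude` (1.5 latent SD): the warm-bay offset. It is spatial
  structure in its own right, so the genuinely unstructured null
  configuration is `spatial_range = 0, bay_amplitude = 0`; that pair is
  what the null-hypothesis tests use.
* `patchiness` (0.4, log scale): spatially coherent per-taxon abundance
  anomalies (patchy habitat such as macrophyte beds), correlation length
  `spatial_range`. This is the ingredient that makes leave-one-out skill
  *spatially inflatable*: with iid assemblage noise, neighbour deletion is
  no more harmful than random deletion and the RNE diagnostic has nothing
  to detect. The default is the value at which the benchmark shows both
  behaviours a realistic training set must show — taxon optima recoverable
  (r ≥ 0.9 for taxa with N₂ ≥ 5) *and* neighbour-deletion r² at or below
  random-deletion r² from 10 km outward in the large majority of seeds.
  Raising it makes the training set more pathological, lowering it more
  ideal.
* `env_block_r` (0.9) and `secchi_r` (−0.9): block loadings. −0.9 rather
  than the −0.8 often quoted for strong temperature–transparency coupling
  because at n = 35 a −0.8 target leaves a substantial chance that the
  empirical correlation falls below the 0.8 grouping rule and the physical
  block fails to reassemble; −0.9 keeps the generative blocks recoverable.
* `count_total` (400–500): the enumeration effort of a standard valve
  count; doubling it measurably shrinks multinomial sampling error, which
  the tests assert.

Determinism: every stage derives its seed from the master seed by hashing
the stage name, so the same configuration yields byte-identical CSVs and
inserting a stage never reshuffles downstream randomness.

**What the generator does not emulate** — taxonomic misidentification,
seasonal succession, sediment taphonomy and mixing, valve-preservation
bias, zero-inflation beyond what multinomial sampling of rare expected
proportions produces, and secondary environmental gradients orthogonal to
temperature. Passing the recovery and RNE tests therefore shows the
*estimators* behave correctly under the assumed response model with
realistic spatial nuisance structure; it does not certify performance on
real assemblages, where response curves are skewed, truncated and
confounded.

## Problem sizes used by the test suite

The suite checks estimator identities on 10–20 random instances of 6–12
sites, the brute-force RDA oracle on 50 instances up to 10 × 6, permutation
calibration on 200 replicate null datasets (n = 35, 199 permutations),
recovery and RNE behaviour on full-size benchmarks (35 × 74) over 10–20
seeds, and the end-to-end pipeline on full-size benchmarks with reduced
permutation counts. These sizes were chosen so the whole suite gives
tight Monte Carlo bounds while staying quick enough to run habitually.

## Known limitations

* Single calibrated variable; no multi-variable or unimodal (CCA-based)
  calibration, no modern-analogue or Bayesian reconstruction, no bootstrap
  errors (jackknife only).
* The permutation test offers free permutation only; restricted schemes for
  structured designs are out of scope.
* `indval`'s combination mode enumerates all group subsets, which is
  exponential in the number of groups — fine for the handful of gradient
  classes it is meant for.
* RNE assumes one deletion geometry (great-circle or linear-transect
  distance); no anisotropy, no h-block variants.
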