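---
title: "Kernel-weighted lasso for subtype-specific methylation–expression networks"
author: "kwlasso"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel-weighted lasso for subtype-specific methylation-expression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kwlasso)
```

## The model

`kwlasso` estimates, per target gene $g$ and per cancer subtype $s^*$, a
sparse linear map from DNA methylation features to expression:

$$
\beta^g_{s^*} \;=\; \arg\min_{\beta}\;
\sum_{s}\; w_{s^*}(s)\,
\bigl\lVert y^g_s - X^g_s \beta \bigr\rVert_2^2
\;+\; \lambda \lVert \beta \rVert_1 ,
$$

where the outer sum runs over all subtypes, $y^g_s$ is gene $g$'s
log-scale expression in the samples of subtype $s$, and $X^g_s$ the
matching methylation features. Every sample participates in every
subtype's fit, but a sample of subtype $s$ enters the $s^*$-specific
objective at the weight

$$
w_{s^*}(s) \;=\; K_h\!\bigl(\mathrm{dist}(s, s^*)\bigr)
\;=\; \exp\!\bigl(-\,\mathrm{dist}(s,s^*)^2 / h\bigr),
$$

an RBF kernel of a between-subtype distance. Target-subtype samples get
weight exactly 1. The estimator interpolates between two familiar
extremes: as $h \to 0$ it degenerates to a separate lasso per subtype, and
as $h \to \infty$ to one pooled lasso that ignores subtypes. The point of
the construction is the small-stratum problem: a subtype with a dozen
samples cannot support its own regression, but down-weighted samples from
related subtypes can stabilise it without erasing its specific structure.

### The distance

The distance between two subtypes is the two-sample Kolmogorov–Smirnov
statistic $D = \sup_x |F_a(x) - F_b(x)|$ between the *pooled* empirical
distributions of all methylation values of all samples in each subtype. It
is distribution-free, lies in $[0,1]$, is invariant to any monotone
transform applied jointly, and needs no model of how subtypes differ. Two
details are deliberate:

* **Pooling.** All values of all samples of a subtype form one empirical
  sample per subtype, so each pair of subtypes needs a single ECDF
  comparison and the result does not depend on sample order. A
  mean-pairwise-sample alternative would weight each sample equally but is
  quadratic in cohort size and much noisier per pair.
* **Statistic, not critical value.** The KS *critical value*
  $c(\alpha)\sqrt{(n+m)/nm}$ depends only on the sample sizes, so it
  cannot encode how dissimilar two subtypes actually are; the
  data-dependent statistic $D$ is the distance. For users who want the
  test-statistic scaling, `subtype_distance_matrix(..., scaled = TRUE)`
  multiplies $D$ by $\sqrt{nm/(n+m)}$.

Distances are computed on the log-normalized methylation matrix after all
filters — the same matrix the models are fit on.

### The solver

The weighted objective is solved directly by cyclic coordinate descent
with covariance updates (`src/cd_lasso.cpp`): for coordinate $j$,
$\beta_j \leftarrow S\!\bigl(g_j, \lambda/2\bigr) / (X^\top W X)_{jj}$ with
$g_j$ the partial residual correlation and $S$ the soft-threshold
operator. Penalty paths are computed warm-started from
$\lambda_{\max} = 2\max_j |\sum_i w_i x_{ij}(y_i - \bar y_w)|$ (the exact
point below which a coefficient first enters) down three decades, 50
log-spaced values. The objective is kept in the printed sum-of-squares
form, so $\lambda$ values are on that scale throughout. Scaling each row
by $\sqrt{w_i}$ and running a plain lasso is algebraically the same
problem; the test suite exploits this as an *independent oracle* (glmnet on
scaled rows agrees with the coordinate-descent solution to $10^{-6}$ or
better), while the package's own solver works on the weighted objective
itself.

Two departures from the bare objective are defaults, both switchable:

* **Intercept** (`intercept = TRUE`): expression data are not centred, so
  an unpenalized intercept is fitted via weighted centring.
* **Standardization** (`standardize = TRUE`): features are scaled to unit
  *weighted* variance before penalisation, making one $\lambda$ comparable
  across features; coefficients are returned on the original scale.

Degenerate inputs have defined behaviour: all-zero weights, negative
weights, and non-finite values are errors; a (weighted-)constant feature
simply can never be selected. A convergence sweep stops when the largest
scaled coefficient update falls below `tol` ($10^{-10}$ by default).

### Choosing λ and h

$\lambda$ is chosen per gene and target subtype by $k$-fold
cross-validation ($k = 5$, folds stratified by subtype, deterministic
given the seed) minimising the *weighted* out-of-fold squared error — the
same weights as the fit, so samples near the target subtype dominate the
choice. Ties break toward the smaller $\lambda$. `rule = "1se"` instead
returns the largest $\lambda$ within one standard error of the minimum;
the minimiser is the right choice for prediction, the one-standard-error
model for support-oriented use, since the CV minimiser is known to keep
spurious features whose coefficients barely affect prediction error.

The bandwidth is a single global $h$ per run, selected by grid search (10
log-spaced points, $10^{-2}$ to $10^{2}$ by default). A subtlety matters
here: the weighted CV error *cannot* be the bandwidth criterion, because
the weights — and therefore the error measure itself — change with $h$;
at $h \to 0$ the "error" silently becomes the separate-fit error of the
target subtype alone, and the grid floor always wins. `select_bandwidth()`
therefore selects $\lambda$ by the weighted criterion (as at fit time) but
scores each candidate $h$ by the held-out prediction RMSE *on
target-subtype samples only* — one fixed yardstick for every candidate.
`cv_rmse(..., h_grid = )` applies the same rule nested inside each outer
training fold, so the evaluation test folds never influence the tuned
bandwidth.

## Evaluation

`cv_rmse()` compares three estimators of the same gene under outer
stratified 5-fold cross-validation: the kernel-weighted fit, a separate
plain lasso per subtype, and one pooled plain lasso. Per-subtype RMSE
pools squared errors over folds and takes a single root at the end —
with a 16-sample subtype, per-fold RMSEs would average one or two test
samples and be dominated by their noise. Subtypes smaller than the fold
count are spread over as many folds as they have samples, so each of
their samples is still held out exactly once. Gene rankings come in two
flavours: best-estimated overall (mean kernel-weighted RMSE across
subtypes, ascending) and most-improved per subtype (pooled minus
kernel-weighted RMSE, descending); pathway scores sum the per-gene
statistic over member genes, once per containing pathway. Top-$k$ ties
break lexicographically so reports are reproducible.

## Networks

Each fitted coefficient with $|\beta|$ above a tolerance ($10^{-8}$ by
default — guarding against numerically-nonzero solver output, not a
relevance threshold) becomes a directed edge methylation-feature → gene in
that subtype's bipartite network. Edge identity is the (feature, gene)
pair regardless of sign or magnitude. The Venn partition classifies every
edge of the union by the exact subset of subtype networks containing it;
cell counts always sum to the union size (asserted in tests), and
"subtype-specific" edges are the size-1 cells. Hub degrees are computed on
the subtype-specific edge set by default — mirroring a network view in
which edges shared by two or more subtypes are removed — with a
`specific_only = FALSE` escape hatch; a hub's total degree always equals
the sum of its per-subtype degrees.

## The synthetic cohort generator

`generate(sim_config())` builds paired methylation/expression data with
known ground truth. What it emulates, and what it deliberately does not:

* **Subtype imbalance.** Default sizes 4/60/10/16 mirror a 16/306/42/73
  cohort scaled down by ~5, keeping the small-subtype phenomenon
  reproducible at desk scale; the heavier property checks run the same
  shape at twice the size ($n = 180$).
* **Positive, log-friendly values.** Log-scale methylation is lognormal
  per entry; stored matrices are $e^{v}-1 \ge 0$, so `log_normalize()`
  recovers the generating scale exactly.
* **Subtype separation.** A per-subtype location shift (0.8 apart by
  default) applied to a random half of the features
  (`shift_fraction = 0.5`) drives the KS distances. Shifting only a subset
  mimics subtype-differential methylation of a limited locus set; shifting
  *all* features would install a single global subtype factor and ~0.55
  mean inter-feature correlation, which real methylation panels do not
  show.
* **Effects.** Features are split into contiguous pathway blocks (4
  pathways by default); each gene's true coefficients live in its block,
  with a shared support (3 features, $|\beta| = 1$, random signs, identical
  across subtypes) plus a small subtype-specific support (2 features per
  subtype, $|\beta| = 0.5$, disjoint across subtypes where the block
  allows). The shared component dominating the specific one is the
  regime the method targets: subtypes as variations on one regulatory
  program. Noise is Gaussian, $\sigma = 0.5$.
* **Not emulated:** CpG autocorrelation, beta-value distributions, probe
  array structure, batch effects, or missingness. Passing tests on this
  generator demonstrates correctness of the machinery and the qualitative
  small-subtype behaviour, not performance on real 450K data.

Everything is a pure function of the config (seed included); fixtures
written by `write_fixture()` are byte-identical across runs.

## Problem sizes used in tests

The test suite and the acceptance script run at desk scale, chosen so the
full suite completes in minutes: solver oracles on 50 random instances
($n \le 60$, $p \le 20$); KS oracles on 100 random pairs; ground-truth
recovery on 20 generated cohorts of $n = 180$, $p = 50$; the three-way
estimator comparison on 20 cohorts with 6 genes each; Venn conservation on
1000 random networks.

## Known limitations

* **Venn-specific edge calling is noisy by construction.** An edge lands
  in a "specific" cell only if its coefficient is nonzero in *exactly one*
  of four independently CV-tuned lasso fits. CV-selected lasso supports
  are not model-selection consistent — each fit keeps a few spurious
  features (measured at roughly 0.1–0.25 selection probability per noise
  feature here) and drops weak true ones, and these errors compound
  multiplicatively across the four networks. On the synthetic cohorts the
  planted shared supports are recovered at better than 90% sign
  consistency, but precision and recall of the planted *specific* edges
  within the Venn specific cells plateau around 0.4 and 0.1 under any
  bandwidth or effect size we examined. Exact specific-cell recovery would
  need a selection-consistent procedure (stability selection, thresholded
  refitting) rather than nonzero-at-CV-λ edge calling; the `rule = "1se"`
  option mitigates but does not resolve this.
* **The smallest subtype bounds specific-effect power.** With $n = 8$ and
  $\sigma = 0.5$, a specific effect of 0.5 has a t-ratio near 2.8 even
  for an oracle fit; no weighting scheme can recover such effects
  reliably, it can only stabilise the shared structure (which is what the
  cross-validated RMSE comparison rewards).
* **One global bandwidth.** A single $h$ per run is cheap and matches the
  tuned-once usage; per-gene or per-subtype bandwidths are plausible
  refinements and are supported implicitly via `cv_rmse(..., h_grid = )`'s
  nested tuning.
* **Pure-noise selection.** On data with no signal, the CV-minimising
  $\lambda$ still keeps a feature or two in roughly half of replicates
  (chance correlations are occasionally CV-predictive; an independent
  solver reproduces the same CV curves). The 1-SE rule returns the empty
  model in most replicates but not all.
* **Scope.** Gene-level symbols only — no probe-coordinate handling, no
  genomic ranges; the probe collapse step expects a ready-made
  probe-to-gene map. The "least correlated probe" rule is interpreted as
  the most negative signed Pearson correlation (promoter-like repressive
  probes), with `rule = "min_abs"` available since the phrase is genuinely
  ambiguous.
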