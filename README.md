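# kwlasso

Subtype-specific associations between DNA methylation and gene expression,
estimated with a kernel-weighted lasso.

## The problem

In heterogeneous cancers, the way promoter methylation regulates a gene's
expression can differ between molecular subtypes — but the subtypes of
interest are often tiny (a few dozen, sometimes under twenty patients), far
too small to fit a separate regression per subtype, while pooling all
patients erases exactly the subtype differences one is after. `kwlasso`
implements the middle road: every sample contributes to every subtype's
model, but at a *learning rate* set by how far its subtype is from the
target subtype.

For a target gene *g* and target subtype *s\**, the coefficients
β<sup>g</sup><sub>s\*</sub> minimise

```
Σ_s  w_s*(s) ‖ y_s − X_s β ‖²  +  λ ‖β‖₁
```

where the sum runs over subtypes, `y_s` is the (log-scale) expression of
gene *g* in subtype *s*, `X_s` the matching methylation features, and the
sample weight is an RBF kernel of a between-subtype distance,

```
w_s*(s) = K_h(dist(s, s*)) = exp( − dist(s, s*)² / h ).
```

The distance is the two-sample Kolmogorov–Smirnov statistic between the
pooled methylation value distributions of the two subtypes — distribution
free, in [0, 1], and requiring no parametric model of what makes subtypes
differ. The bandwidth `h` interpolates between separate per-subtype
estimation (h → 0) and one pooled model (h → ∞), and is chosen by
cross-validation. Features for each gene are restricted to genes sharing a
(KEGG-style) pathway with it; the fitted nonzero coefficients define
per-subtype bipartite methylation → expression association networks, which
are compared across subtypes by a Venn partition of their edges and
summarised by hub degrees.

Intended users: computational biologists modelling regulatory differences
across tumour subtypes (or any stratified cohort with a small-stratum
problem), and methodologists who want a compact, fully tested reference
implementation of sample-weighted L1 regression with kernel weights.

## Worked example

```r
library(kwlasso)

# a synthetic four-subtype cohort with known ground truth
bundle <- generate(sim_config(seed = 3))
expr <- log_normalize(bundle$expr)   # log(T + 1)
meth <- log_normalize(bundle$meth)

# KS distances between subtypes, then kernel weights
d <- subtype_distance_matrix(meth, bundle$sa)
round(d, 2)
#>                HER2 LuminalA LuminalB TripleNegative
#> HER2           0.00     0.38     0.48           0.50
#> LuminalA       0.38     0.00     0.31           0.45
#> LuminalB       0.48     0.31     0.00           0.29
#> TripleNegative 0.50     0.45     0.29           0.00

designs <- build_all_designs(expr, meth, bundle$pc)$designs
h <- select_bandwidth(designs[1:3], bundle$sa, d, seed = 3)$h
sk <- subtype_kernel(d, h)
round(sk$weights["HER2", ], 4)  # per-subtype contribution to the HER2 fit
#>           HER2       LuminalA       LuminalB TripleNegative
#>         1.0000         0.0056         0.0002         0.0001

fits <- fit_all(expr, meth, bundle$pc, bundle$sa, sk, seed = 3)
fits
#> kwl_fits: 40 fits (0 skipped genes), h = 0.0278256

net <- build_networks(fits)
venn_partition(net)
#> venn_partition: 122 edges in union; 18 subtype-specific; 28 in all subtypes
hub_degrees(net, "methylation", top_k = 3)
#>   node total HER2 LuminalA LuminalB TripleNegative
#> 1 MF01     2    2        0        0              0
#> 2 MF04     2    1        1        0              0
#> 3 MF15     2    0        1        0              1
```

The KS distances (0.29–0.50) translate at the tuned bandwidth into small
off-target weights here — on this cohort the subtypes are well separated,
so each fit borrows only lightly; with closer subtypes or a wider-scoring
bandwidth grid the weights move toward 1 and the fits share more strength.

`fit_all` returns one sparse coefficient vector per (gene, subtype); the
network stage turns every coefficient with |β| above a tolerance into a
directed edge methylation-feature → gene, partitions edges by the exact set
of subtypes in which they occur (the Venn cells; "subtype-specific" means
present in exactly one), and ranks hub features by degree. The
`evaluate_genes()` function compares the kernel-weighted estimator against
separate per-subtype and pooled lasso baselines by stratified
cross-validated RMSE; on the synthetic cohorts the improvement over
separate estimation is concentrated in the smallest subtype, which is the
point of the method.

A command-line wrapper (`inst/scripts/kwlasso`) chains the stages
`simulate → preprocess → distances → fit → evaluate → network` from a YAML
config; see the methods vignette for the model details and design choices.

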