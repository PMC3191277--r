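---
title: "Modelling a normality boundary for brain-activation patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a normality boundary for brain-activation patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocboundary)
```

## The problem

Group-level neuroimaging statistics tell us where patients differ from
controls *on average*; they do not tell us how atypical one individual's
pattern of brain activation is. `ocboundary` treats that question as
one-class classification: learn, from healthy controls only, the boundary
of the distribution of "normal" activation patterns, then score any new
subject by a signed surrogate of their distance to that boundary. Subjects
outside the boundary are outliers; how far outside they fall is a graded
measure of abnormality that can be correlated with clinical scores.

The one-class approach needs no patient data at training time, which makes
it attractive when patient samples are small, heterogeneous, or carry
uncertain diagnoses — exactly the settings where a two-class classifier is
unreliable.

## The model

Each subject is represented by a pattern vector $x \in \mathbb{R}^p$ built
from condition-wise GLM coefficient ("beta") images: either every in-mask
voxel or every atlas-region mean, concatenated across task conditions. The
$\nu$-one-class SVM with a Gaussian kernel
$k(x, y) = \exp(-\gamma\lVert x - y\rVert^2)$ solves the dual

$$
\min_\alpha \tfrac12 \alpha^\top K \alpha
\quad\text{s.t.}\quad 0 \le \alpha_i \le \tfrac{1}{\nu n},\;
\textstyle\sum_i \alpha_i = 1 ,
$$

and classifies a new pattern by
$f(x) = \sum_i \alpha_i k(x_i, x) - \rho$, outlier iff $f(x) < 0$. Because
$k(x, x) = 1$, all patterns live on the unit sphere of the implicit
feature space, where the smallest enclosing hypersphere and the
maximum-margin separation from the origin coincide. The parameter $\nu$
upper-bounds the fraction of training outliers and lower-bounds the
fraction of support vectors.

The dual is solved by an in-house sequential minimal optimisation routine
(compiled): maximal-violating-pair selection on the gradient
$g = K\alpha$, feasible start $\alpha_i = 1/n$, stop when the KKT
violation falls below $10^{-6}$ or after $10^4$ pairwise updates. The
offset $\rho$ is the mean of $g_i$ over margin support vectors
($0 < \alpha_i < \tfrac{1}{\nu n}$, identified with an $10^{-8}$ slack on
$\alpha$); when no strict-margin vector exists, the midpoint of the
KKT-feasible interval is used. The test suite checks this solver against
an independent interior-point QP solve on random instances, so its
convergence contract is empirical as well as stated.

### Width-parameter convention

Toolboxes disagree about whether the Gaussian kernel is parameterised by
$\gamma$ or by a length scale $\sigma$. This package canonicalises on
$\gamma$ and exposes the conversion
$\gamma = 1/(2\sigma^2)$ (`sigma_to_gamma()`, `gamma_to_sigma()`). That
convention is this package's own documented choice; when comparing with
software that defines $\sigma$ differently, convert explicitly.

## Hyperparameter selection

`nested_loo()` reproduces a fully nested leave-one-out protocol. Each outer
fold holds out one positive-class subject and its pair-matched
negative-class subject. On the remaining positives, `two_step_search()`
runs an exhaustive inner leave-one-out twice: first $\gamma$ is chosen with
$\nu$ fixed at 0.1, then $\nu$ is chosen with $\gamma$ fixed. Inner
"accuracy" is the fraction of held-out positives classified non-outlier —
a deliberate, documented choice, since only positive-class subjects exist
inside the inner loop; the $\nu$ constraint prevents the trivial boundary
that would declare everyone normal. A joint 2-D search is available as
`mode = "joint"` for comparison.

Tie-breaks are explicit: equal-accuracy ties on the kernel width resolve to
the largest $\gamma$ — the smallest length scale $\sigma$ under the
convention above — and ties on $\nu$ resolve to the smallest value (the
loosest boundary, sacrificing the fewest training subjects). The default
grids are $\nu \in \{0.1, \dots, 0.5\}$ and $\gamma$ log-spaced over
$10^{-7} \dots 10^{-3}$, five points per decade.

After cross-validation, `final_model()` refits once on *all* positives
with the averaged fold parameters — geometric mean for $\gamma$ (it lives
on a log grid), arithmetic mean for $\nu$ — so that every patient is scored
against one common boundary and their decision values are mutually
comparable. That single-model scoring is what the severity correlation and
the weight maps use.

## Significance, severity, subgroups

`permutation_test()` reassigns the group labels uniformly at random
(preserving group sizes) and re-runs the entire outer cross-validation per
permutation. The p-value for the true-positive ratio is the fraction of
permutations with a ratio *at least* the observed one — ties count against
the observed statistic, the conservative reading — using the plain
count/B estimator by default (`plus_one = TRUE` switches to
$(\text{count}+1)/(B+1)$). Because the two-step search dominates the cost,
`fast_null = TRUE` reuses the observed run's averaged $(\gamma, \nu)$ for
the permuted runs; the default repeats the full search. Under a permuted
labelling, pairs that still straddle the two groups keep their original
`pair_id`; leftover positives are matched to leftover negatives by a
seeded random assignment, so the matched-fold structure is preserved.

`severity_correlation()` reports the Pearson correlation (two-sided
t-transform p, $n-2$ df) between patient decision values and severity,
over all patients or the responder/non-responder subsets;
`subgroup_table()` tabulates treatment response by outlier status, with
empty cells reported as missing rather than zero.

## Spatial maps

The model weight $w = \sum_i \alpha_i \Phi(x_i)$ has no exact input-space
counterpart under the Gaussian kernel, so `weight_map()` computes its
approximate pre-image: the point $z$ minimising
$\lVert\Phi(z) - \sum_i \alpha_i \Phi(x_i)\rVert^2$, by the fixed-point
iteration
$z \leftarrow \sum_i \alpha_i k(z, x_i)\, x_i \big/ \sum_i \alpha_i k(z, x_i)$.
Numerical safeguards: steps that would increase the objective are damped by
halving (so the accepted objective sequence is non-increasing); underflow
of all kernel weights restarts from the $\alpha$-weighted support-vector
mean; and because the fixed point is only local, the iteration runs from
that weighted mean plus five seeded random starts, keeping the best
objective. Convergence is declared when the iterate moves less than
`tol * (1 + ||z||)`. These choices — restart count, damping, stopping rule
— are this package's own contract; diagnostics (objective trace, gradient
norm, per-start table) are returned for audit.

The pre-image vector is unflattened through the recorded feature index
into one volume per condition (voxel features) or painted region tables
(region features). `rescale_map()` divides each condition map by its
absolute maximum so colour scales run from $-1$ to $+1$ with signs
preserved; rescaling is idempotent and applied per condition map.
`one_sample_tmap()` supplies the univariate second-level comparison:
$t = \bar{x}/(s/\sqrt{n})$ per feature, $n-1$ df, unthresholded, with
zero-variance features reported as $t = 0$ and flagged. Weight maps
visualise a multivariate decision boundary; they are not statistical tests
of activation, and the output metadata carries that caveat.

## The synthetic cohort generator

`simulate_cohort()` produces fully synthetic cohorts with the statistical
structure the framework assumes, so every stage is testable without
clinical data:

* a shared baseline activation pattern per condition (voxelwise
  $N(0, \texttt{pattern\_sd}^2)$, default SD 3 beta units), expressed by
  each subject at an individual amplitude $a_s \sim N(1, 0.1^2)$;
* iid voxel noise, default SD 0.5 beta units;
* patients additionally carry $\text{severity} \times
  \texttt{deviation\_scale} \times D$, where $D$ is a fixed sparse
  deviation pattern on ~10% of in-mask voxels with $\pm 1$ signs — sparse
  so that both voxel- and region-based features carry signal, mirroring
  localised group differences;
* severity uniform on 18–25 HRSD points plus truncated $N(0, 1)$ noise
  (the acute-episode inclusion range; controls sit near zero);
* a simulated post-treatment score equal to severity minus a
  subgroup-specific effect (16 points for the low-severity half, 8 for the
  high, plus $N(0,2)$ noise); response means falling below 10 points.
  Low-deviation patients therefore tend to respond, reproducing the
  two-subgroup structure qualitatively;
* an ellipsoidal brain mask on a $12^3$ grid (~700 in-mask voxels) and a
  20-region contiguous-block atlas; age/sex matching is abstracted into
  shared pair identifiers.

Two design points deserve emphasis. First, the per-subject amplitude term
is essential, not cosmetic: with iid voxel noise alone, high-dimensional
distance concentration makes every held-out subject equally — and
maximally — atypical (the margin support vectors' self-similarity advantage
always wins), so the true-negative ratio degenerates to zero at any kernel
width and the permutation null becomes constant. Real coefficient images
do not behave that way because subjects genuinely differ in overall
response amplitude; the generator encodes that mechanism explicitly.
Second, the default deviation scale (0.2 beta units per HRSD point) is
chosen so that the planted linear severity coupling dominates the
amplitude and voxel noise at this grid size; that is the regime the
severity-recovery property is meant to certify.

What the generator does **not** emulate: spatial autocorrelation and
smoothness, anatomy, hemodynamics, site or motion artefacts, or covariate
structure beyond pairing. Passing tests therefore certify the algorithmic
pipeline — solver optimality, protocol fidelity, calibration under
exchangeability, map algebra — not performance on real fMRI data.

### Feature kind and kernel scale

The default grids match the squared-distance scale of voxel-based patterns
(a few thousand, for ~2000 dimensions at these noise levels), where
$\gamma \lVert x - y\rVert^2$ spans the useful range. Region averaging at
desk scale shrinks squared distances by roughly the region size, pushing
all grid kernels into the degenerate $K \approx 1$ regime where every
held-out subject is marginally an outlier. Region features remain fully
supported — with full-resolution inputs their distance scale is comparable
to the grid again — but the package's default analyses and the worked
examples use voxel features. If you bring region features at another
scale, widen the $\gamma$ grid accordingly (`search_grid()`).

## Problem sizes and determinism

The shipped analyses use the 19 + 19 cohort on the $12^3$ grid; the test
suite exercises the solver on instances up to $n = 50$, the severity
property over 20 cohort seeds, and the permutation-null calibration over
50 replicates of 200 permutations with the fast null. All randomness flows
from one root seed through named substreams (cohort, permutations,
pre-image restarts), so identical configuration and seed reproduce every
output byte for byte — including the JSON summary written by
`run_pipeline()`.

## A worked run

```{r example, eval = FALSE}
library(ocboundary)

co <- simulate_cohort(cohort_spec(seed = 1))
feats <- voxel_features(co$volumes, co$mask)

cv <- nested_loo(feats, co$table, search_grid())
glance(cv)

controls <- co$table$subject_id[co$table$group == "control"]
patients <- co$table$subject_id[co$table$group == "patient"]
model <- final_model(feats[match(controls, rownames(feats)), ], cv)

report <- decision_values(model, feats[match(patients, rownames(feats)), ])
severity_correlation(report, co$table, "all")
subgroup_table(report, co$table)

wmap <- rescale_map(weight_map(model, co$mask, seed = 1))
autoplot(wmap)
```

## Known limitations

* The inner-loop accuracy definition is necessarily one-sided (positives
  only); other definitions would change which hyperparameters win ties.
* Permutation p-values inherit the granularity of the fold count
  (multiples of $1/19$ here) and of $1/B$; they are discrete and
  conservatively super-uniform by construction.
* The pre-image is a local optimum of a non-convex objective; restarts
  reduce, but cannot eliminate, dependence on initialisation.
* Decision-value magnitudes are comparable only against a fixed model;
  across refits, compare ranks or refit-consistent summaries.
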