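---
title: "Significance-weighted SVM-RFE: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Significance-weighted SVM-RFE: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigrfe)
```

## The problem

Two-class expression studies (tumor vs. normal arrays, treated vs.
untreated cultures) routinely have tens of thousands of features and a few
dozen samples; the samples-to-dimensions ratio is on the order of 10^-3
(`dataset_characteristics()` lists typical values). Feature selection in
this regime has two failure modes that `sigrfe` addresses jointly:

1. selecting features that help the classifier but are not differentially
   expressed between the groups, which frustrates downstream biological
   interpretation; and
2. instability — the selected set changing wholesale when a handful of
   samples are swapped.

## The ranking model

The core procedure is recursive feature elimination driven by a linear
soft-margin SVM. With decision function
$f(x) = \sum_{j=1}^{d} w_j x_j + b$, the weight vector is reconstructed
from the dual solution, $w = \sum_k \alpha_k y_k x_k$ (an invariant the
test suite checks at every iteration of a small run). Classical SVM-RFE
scores feature $i$ by $w_i^2$ alone. Here the default criterion also asks
whether the feature separates the classes marginally:

$$ c_i = w_i^2 \, (1 - p_i), $$

where $p_i$ is the two-sided tail probability
$P[t_i(v) < -|u| \text{ or } t_i(v) > |u|]$ of the per-feature Welch
two-sample $t$ statistic (unpooled variances, Satterthwaite degrees of
freedom $v$). A feature survives elimination only if it carries classifier
weight *and* a small marginal p-value. Each iteration retrains the SVM on
the survivors, computes $c$, and removes the
$\max(1, \lceil E/100 \cdot |s|\rceil)$ lowest-criterion features; the
output is a full permutation with rank 1 the feature removed last.

Three criterion modes are exposed by `recursive_eliminate()`:

* `significant` (default): $c_i = w_i^2 (1 - p_i)$.
* `rfe`: $c_i = w_i^2$, the weight-only baseline (`svm_rfe()`).
* `literal`: $c_i = w_i \, p_i$, the raw weight-times-tail-probability
  product. Taken literally this removes small-weight, *small-p* features
  first — i.e. it discards the significant ones — which contradicts the
  declared goal of significance-aware selection. We keep it for fidelity
  and comparison, but `significant` is the default because it is monotone
  in both $|w_i|$ and the evidence against the null; on planted-signal
  simulations the suite verifies that `significant` front-loads smaller
  p-values than `rfe` does.

When one class is a singleton the Welch statistic is undefined and the
larger group is tested against a reference mean (by default the
singleton's observed value) with a one-sample $t$; both-singleton input is
an error. Degenerate variances never crash: two constant equal groups give
$t = 0, p = 1$; constant but different groups get $p$ set to the machine
epsilon (maximal significance). Criterion ties are broken by eliminating
the smaller feature index first, making every ranking byte-reproducible.

## Ensemble selection and stability

The elimination procedure is deterministic, so diversity comes from
resampling: `make_bootstrap_plan()` draws $k$ subsamples of
$\lceil x M \rceil$ samples with replacement (defaults $k = 40$,
$x = 0.9$), stratified so each subsample preserves the class proportions
and keeps at least two samples per class — unstratified resampling at
these sample sizes regularly produces untrainable single-class draws.
Per-bootstrap seeds follow `seed_i = master_seed + i` and are recorded in
every provenance file. Because of stratification, the expected number of
distinct samples per bootstrap is the per-stratum expression
$\sum_c n_c (1 - (1 - 1/n_c)^{\text{draws}_c})$, which the tests verify
against simulation.

Per-bootstrap rankings are combined by complete linear aggregation
(`aggregate_cla()`): feature $j$'s ensemble score is
$f_j = \sum_i w_i f_{ij}$, the (optionally weighted) sum of its rank
positions. Since rank 1 is best, the *smallest* aggregated sum identifies
the consensus-best features; a phrasing that selects the largest sum would
pick the consensus-worst, so the package sorts ascending (ties by feature
index). With unit weights the totals conserve $k\,N(N+1)/2$, a property
the tests exploit as an oracle. `extract_signature()` takes the top $s$
(count or percentage, default 10%).

Signature stability across subsamplings is quantified by the Kuncheva
index,

$$ KI(f_i, f_j) = \frac{r - s^2/N}{s - s^2/N}, \qquad r = |f_i \cap f_j|, $$

whose $s^2/N$ term subtracts the expected chance overlap; $KI \in (-1, 1]$
with 1 iff the signatures coincide and mean 0 for random signatures.
`total_stability()` averages all $k(k-1)/2$ pairs;
`reference_pairwise_stability()` compares everything to one reference list
(default the first bootstrap's signature — the choice is arbitrary and
configurable). The index is computed on feature identifiers, never on
positions, so aggregation order cannot affect it.

## Honest performance estimation

`external_cv_error()` implements external cross-validation: inside each
stratified fold the entire selection procedure is re-run on the training
part only, the evaluation classifier is trained on those features, and
error is scored on the held-out part. The evaluation classifier is an
RBF-kernel SVM — distinct from the linear machine inside the elimination
loop — optionally tuned by an exhaustive inner-CV grid over cost and gamma
(`tune_rbf_grid()`, default grids $2^{-5..15}$ and $2^{-15..3}$ in steps
of 2, ties resolved toward the smaller cost then smaller gamma). The
deliberately biased alternative (`protocol = "naive"`, selection once on
the full data) is provided because the contrast matters: on label-permuted
data the external protocol stays near the chance error of 0.5 while the
naive protocol drops well below it, the classic selection-bias effect the
test suite demonstrates. When tuning is disabled the classifier uses a
fixed cost and gamma $= 1/s$; the selection-bias demonstration uses this
fast path since the effect does not depend on tuning.

`rank_position_pvalues()` profiles ranking quality differently: entry $j$
is the mean (over bootstrap lists) of the unadjusted two-sided p-value of
the feature each list places at rank $j$. P-values are unadjusted by
design — the profile is descriptive, not inferential — and are computed
once on the full data set; a bootstrap-restricted variant would conflate
resampling noise with ranking quality.

## Quantile normalization

`quantile_normalize()` (via limma) maps every sample column onto the
common reference distribution formed by row means of the sorted columns;
ties within a column receive the mean of the reference values over the
tied rank range. The operation is idempotent and equalizes column means
exactly, both asserted in the tests. Normalization is applied to the full
matrix before any resampling, replicating the conventional workflow; note
that this lets held-out samples influence the reference distribution — a
mild information leak that external CV of the *selection* step does not
remove. Callers who consider it material can normalize per training part
and pass `normalize = FALSE` to the pipeline.

## The synthetic-data generator

`simulate_two_class()` emulates quantile-normalized log2 microarray data:
per-feature baseline means drawn once from a wide uniform range (default
4–10, wide enough that normalization has real work to do in tests),
within-class Gaussian noise of standard deviation `sigma`, and a planted
set of informative features shifted by `+delta * sigma` in the positive
class. Class sizes may be unequal. Options cover equicorrelated
informative blocks (`rho`, shared-factor construction) and Student-t noise
scaled to variance `sigma^2` for heavy-tail robustness checks. The
generator does **not** emulate probe-level artifacts, batch effects,
intensity-dependent variance, or count data, so passing tests demonstrate
correct behavior of the algorithms under their nominal model, not
performance on any particular real platform.

Default validation conditions used throughout the suite: 30+30 samples,
300 features with 15 informative at a 2-sigma shift for recovery studies
(with a 10-bootstrap ensemble over 10 master seeds); 20 informative of 300
for the p-value-profile direction check; 30+30 samples and 50 features for
the label-permutation selection-bias demonstration. These sizes keep each
property within a few minutes on one CPU while leaving the effects far
from the assertion thresholds (observed mean recovery ≈ 0.99 against a
0.8 bound; the significance-weighted mode won the p-value direction
comparison in 10 of 10 replicates against an 8-of-10 bound).

## Numerical and design notes

* Default SVM cost is 10 — moderate regularization, the common choice for
  RFE on pre-normalized expression matrices. No internal feature scaling
  is performed: the data are assumed quantile-normalized, and rescaling
  would silently change every $w$-based ranking.
* Whether the original formulation intends $w$, $|w|$ or $w^2$ in the
  criterion product is ambiguous; all three behaviors are reachable
  through the `mode` argument rather than guessed at.
* Welch (unpooled) degrees of freedom are used throughout, matching R's
  default two-sample `t.test()`.
* The bootstrap is with replacement by default;
  `with_replacement = FALSE` provides a subsampling variant for
  sensitivity analysis.
* `run_pipeline()` chains normalize → ensemble rank → signature →
  stability → external CV → p-value profile, writes plain-text artifacts
  plus a JSON provenance record (config, hash, seeds, package version),
  and reproduces byte-identical outputs for identical configurations. Any
  stage failure aborts with the stage name; artifacts written before the
  failure are retained.

## Limitations

* Only binary classification; nonlinear-kernel RFE is out of scope
  (weights are undefined there).
* Statistical stability claims (ensemble ≥ single-bootstrap stability)
  are tendencies over repetitions, not guarantees for a single data set.
* The Kuncheva index compares equal-size signatures only; comparing
  signatures of different sizes requires a different index.
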