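---
title: "Model-averaged differential expression with stability selection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-averaged differential expression with stability selection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmadex)
```

bmadex implements the inference chain of a small case/control
expression-profiling study of benign breast epithelium: usual-risk controls
from reduction mammoplasty (RM), histologically normal epithelium from
breasts harbouring a cancer (HN), and a small high-risk group from
cancer-free prophylactic mastectomy (PM). The chain is: detection-based
probe filtering and mean-200 rescaling; a Bayesian model-averaged score of
differential expression per probe set; leave-one-out stability selection at
a controlled false discovery rate; permutation-tested hierarchical
clustering of the third group against the selected signature; and
delta-delta-Ct qPCR validation. This vignette records the model, the
tunable parameters, and the design decisions taken where the procedure was
genuinely open.

## Preprocessing

Two rules only, applied in this order on MAS5-style linear intensities:

* `filter_detection()` removes probe sets whose fraction of Present calls
  across *all* arrayed samples is strictly below 20%. A probe at exactly
  20% is retained (the removal rule is a strict "less than"). Marginal
  calls count as *not* detected by default - a conservative reading of the
  MAS5 call semantics - switchable with `marginal_as_detected = TRUE`.
  Filtering happens once, jointly over the groups, before any comparison.
* `rescale_samples()` multiplies each sample by a scalar so its mean
  intensity is 200. Nothing else: no background correction, no quantile or
  loess step. The operation is idempotent, and because the filter ignores
  intensities, filtering and rescaling commute up to one final rescale.

One consequence worth knowing: mean rescaling is compositional. If a large
fraction of probes changes in one direction, rescaling shifts every other
probe's apparent level in the opposite direction. At a realistic scale
(about 100 differential probe sets out of about 13,000) the shift is
negligible; on a 100-probe simulation with 10% planted one-directional
folds it dominates. The package's accuracy tests therefore score the
generator's raw output, and simulations meant to be rescaled keep the
differential fraction small.

## The model-averaged score

For each probe set, intensities in the two groups are modelled by two
families the data cannot easily distinguish a priori:

* **lognormal**: log intensities are normal with unknown mean and variance.
  The prior is conjugate normal-inverse-gamma: the prior mean is the
  probe's pooled log mean with `kappa0 = 0.1` effective observations; the
  variance prior is inverse-gamma with shape `a0 = 0.5` and scale
  `b0 = a0 *` (pooled log-scale variance). Posterior draws and the marginal
  likelihood are closed-form; the marginal carries the Jacobian to the
  observed linear scale so it is comparable across families.
* **gamma**: intensities are gamma with unknown shape and rate. The
  posterior is handled by a Laplace approximation in (log shape, log rate)
  around the posterior mode, with importance-weighted draws correcting the
  Gaussian approximation; the marginal likelihood is the Laplace evidence.
  The prior is normal with sd 3 on both log parameters, centred at the
  pooled-data estimate.

Family weights are proportional to the product of the two groups' marginal
likelihoods under that family. The *probability score* of a probe is
`1 - max(P(fold > 1), P(fold < 1))`, where the fold is the ratio of
linear-scale group means and the probability is the weight-averaged
fraction of posterior fold draws above 1. The point fold estimate is the
weighted posterior median of the draws, robust to the ratio's skew.

Two properties follow directly from that definition and matter for
interpreting thresholds downstream:

* the score lives in [0, 0.5], not [0, 1];
* on null data it is approximately uniform on [0, 0.5] (equivalently,
  twice the score is uniform on [0, 1]). About 10% of null probes score
  below 0.05 - twice what a classical two-sided p-value would give. The
  score is a posterior error probability for the *direction*, not a
  frequentist two-sided p-value, and the stability wrapper below exists
  precisely because thresholding it alone is permissive.

### Why the priors are scaled to the data

An earlier fixed choice (inverse-gamma(0.5, 0.5) on the log-scale variance,
a zero-centred sd-10 prior on the gamma log parameters) made the family
weights reflect prior normalisation constants instead of fit: at a
coefficient of variation of 0.2 the observed log-scale variance is about
0.04, where the fixed inverse-gamma density is about e^-12, so the
lognormal family lost to gamma on lognormal data. Scaling `b0` to the
pooled log-scale variance and centring the gamma prior on pooled estimates
removes the arbitrary constants; both families then receive the same kind
of weakly-informative, data-located prior. With that calibration the
lognormal family wins on lognormal data essentially always, and the gamma
family wins on clearly gamma data (high dispersion). At low dispersion
(cv around 0.2) the two families are near-identical normal perturbations
and the weights carry little information - no procedure could distinguish
them there, and nothing downstream depends on doing so.

### Determinism and draws

Every probe derives its own seed from the global `badge_config()` seed and
the probe id, so scores are independent of evaluation order and stable
under parallel or subsetted evaluation. `n_draws` controls Monte Carlo
resolution; the smallest representable nonzero score is `1/n_draws`.
Because the per-run selection threshold of the stability wrapper sits
around 1.5e-3 (see below), production runs should use at least 4,000 draws
so that granularity near the threshold does not inflate selections; 10,000
(the default) is comfortable. Intensities at or below zero are floored at
`epsilon = 1` before logs.

## Stability selection

`loo_stability()` wraps the scorer in leave-one-out cross-validation: one
run per left-out sample (36 runs for an 18 + 18 design; a paired mode
removes one matched pair per run instead). Each run applies
Benjamini-Hochberg to the probability scores of the remaining samples and
selects probes with adjusted value strictly below 6%; probes selected in at
least 80% of runs form the signature. Final scores, folds and companion
two-sided log-scale t-tests are computed once on all samples. The procedure
names no multiple-testing rule for the per-run step, so Benjamini-Hochberg
was chosen as the standard monotone step-up; both thresholds follow the
stated wording ("<" for the FDR, ">=" for the frequency).

On synthetic data at the study's scale (2,000 probes, 50 planted 3-fold
changes, cv 0.2, 18 vs 18) the wrapper attains sensitivity 1.0 with about
4-6 false positives, and on pure-null data it never selects more than the
single-run selection does - the wrapper's purpose is cutting the
permissiveness of thresholding the raw score.

## Cluster concordance and the permutation test

`hcluster_samples()` clusters samples on `log2(intensity + 1)` Euclidean
distances with average linkage (both switchable: correlation distance,
complete linkage). The log transform prevents the brightest probes from
dominating; the procedure's source names none of these choices, so they
are explicit, deterministic defaults. Agglomeration is implemented with a
documented tie-break - among equally close pairs, the pair containing the
lowest original sample indices merges first - because the contract
requires bit-reproducible trees even on degenerate (tied) input; on
tie-free data it agrees with `stats::hclust` exactly (verified against
cophenetic distances in the tests).

`cut_two()` removes the final merge to give a two-block partition.
`concordance_pattern()` summarises a cluster result as the count of
focal-group samples inside and outside the block holding the majority of an
anchor group (majority ties break towards the block containing the
first-listed sample). `permutation_cluster_test()` computes the tree once -
permuting labels cannot change distances - then redraws the label
assignment uniformly 10,000 times (the identity assignment is not
excluded) and counts permutations whose pattern *equals* the observed one;
an `"at-least"` mode counts patterns at least as concordant instead, giving
a conservative p-value-like frequency. On a balanced 4 + 4 design with
perfect separation the exact match probability is 2/C(8,4) = 1/35, which
the implementation reproduces against exhaustive enumeration.

## qPCR validation

dCT is the test-gene CT minus the reference-gene CT per sample; ddCT is
the test-group mean dCT minus the reference-group mean dCT; fold change is
`2^-ddCT` with amplification efficiency assumed exactly 2. The sign
convention is stated once and unit-tested: lower dCT means higher
expression, so a microarray fold above 1 in the reference group predicts
test-sample dCT *above* the reference mean. A reaction validates when the
sample's dCT falls strictly on the predicted side; exact ties do not
validate. Group comparisons use a one-tailed pooled-variance t-test with
the tail set by the predicted direction. Missing CTs are simply absent
rows and drop pairwise.

## The synthetic-data generator

`generate_expression()` emulates what the analysis assumes about real
arrays: per-probe lognormal baselines (log-mean 5, log-sd 1, i.e. typical
intensities of about 150 on the MAS5 scale), within-group intensities drawn
lognormal (or gamma, to probe mis-specification) with a common coefficient
of variation, planted linear-scale folds uniform on [2, 6] (the printed
signature's spectrum) with the up-in-RM direction at probability 2/3
(matching the observed 66:32 split), group sizes 18/18/6, and
Bernoulli Present/Absent calls (0.9 for expressed probes, 0.05 for
unexpressed; an intensity-linked mode ties Absent calls to the dimmest
decile). PM samples copy the HN-relative direction and magnitude of every
planted fold, the structure the third-group analysis looks for. The
generator emits *unscaled* intensities - the pipeline's own rescaling is
part of what is under test. A single seed drives a splittable per-stage
generator, so runs are bit-reproducible.

What it does not emulate: probe-level cross-hybridisation, spatial chip
artefacts, correlated probe blocks, intensity-dependent variance, or
detection calls linked to expression level (except in the optional mode).
Passing tests on this generator show the chain's statistical logic is
sound under its own assumptions; they do not certify performance on real
arrays, where none of those idealisations hold. The within-group cv
default of 0.25 is a modelling choice - the source material never
characterises within-group variance - picked as typical for replicate
microdissected epithelium profiles.

`generate_ct_table()` plants qPCR folds as exact dCT shifts
(`-log2(fold)`) plus Gaussian per-reaction noise, with per-sample CT
offsets that cancel in the dCT, so closed-form recovery at zero noise is
testable exactly.

## Problem sizes used by the packaged checks

The acceptance script and the end-to-end tests run: null calibration on
2,000 probes at 2,000 draws; stability selection on 2,000 probes times 37
scoring passes at 4,000 draws (the dominant cost, a few minutes); the
permutation oracle at 100,000 permutations of 8 samples; and qPCR cohorts
of 6 genes times 25 samples. These sizes keep every quantity's Monte Carlo
error well inside the bands being asserted while the whole suite stays in
the minutes range.

## Known limitations

* The score's null distribution is uniform on [0, 0.5]; consumers
  expecting classical two-sided p-values will find nominal thresholds
  about twice as permissive. The stability wrapper compensates
  operationally but does not change the score's meaning.
* Family weights are uninformative at low dispersion (see above).
* The exact families and priors of the original model-averaging software
  are documented only in its own methods reference; this package fixes
  reproducible weakly-informative defaults and claims orientation and
  approximate magnitude of printed folds, not numeric identity.
* Mean rescaling is compositional; see Preprocessing.
* The cluster test's "matching" criterion is exact pattern equality by
  default; the at-least mode exists because both readings are defensible
  and the source does not say which was used.
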