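---
title: "Methods: P-P interval variability and variance-correct oversampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: P-P interval variability and variance-correct oversampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flutterppi)
```

## The problem

Atrial flutter (AFL) is sustained by one of two mechanisms. In macroreentrant
AFL (MAFL) the activation wavefront circulates a large anatomical obstacle on
a stable loop; in focal AFL (FAFL) depolarization originates at a point
source and spreads centrifugally, without a guaranteed repeat path. Knowing
the mechanism before catheter ablation shortens the invasive mapping stage,
but the mechanism is hard to read off the 12-lead surface ECG directly.

The working hypothesis of this package is purely temporal: a stable loop
should produce stable P-to-P intervals, a focal source more variable ones.
The pipeline therefore classifies records from descriptive statistics of
each record's P-P interval series alone — no delineation or morphology of
the atrial waves is used. Intervals above 300 ms are treated as false
intervals (spanning a missed wave) and removed; exactly 300 ms is kept, a
literal reading of "above".

Clinical AFL cohorts are small and imbalanced (the motivating population
is 41 MAFL against 5 FAFL records, about 8:1). A classifier fitted naively
to such data buys accuracy by defaulting to the majority class: sensitivity
(MAFL recall) looks excellent while specificity (FAFL recall) collapses.
The package's core is a comparison of three minority-oversampling schemes
that generate synthetic interval *series*, together with the machinery to
validate, select and evaluate them.

## The three samplers

Let $X_j$ be an anchor interval drawn from a minority record's series and
$X_k$ a neighbor drawn uniformly from a pool excluding the anchor instance
(the neighborhood is the whole pool, $k = N - 1$, not a local k-NN search).
With $\alpha \sim U(0,1)$:

* **SMOTE**: $S = X_j + \alpha\,(X_k - X_j)$. The draw lies on the segment
  between anchor and neighbor.
* **Modified SMOTE**: $S = X_j + \tfrac{3}{2}\alpha\,(X_k - X_j)$. The draw
  may overshoot the neighbor by up to half the segment.
* **Smoothed bootstrap**: $S = X_j + h Z$ with $Z \sim N(0,1)$ and $h$ a
  Gaussian-kernel bandwidth (Silverman's rule by default, or fixed). At
  $h = 0$ this is the classic bootstrap, whose sampling distribution is the
  empirical step function; $h > 0$ renders it continuous.

### Why 3/2

For i.i.d. data and a coefficient $c$ on the interpolation step,
$S = (1 - c\alpha) X_j + c\alpha X_k$ has

$$\operatorname{Var}(S) = \left(1 - c + \tfrac{2}{3}c^2\right)\sigma^2 ,$$

using $E[\alpha] = \tfrac12$, $E[\alpha^2] = \tfrac13$. Classic SMOTE is
$c = 1$, giving the well-known variance shrinkage to $\tfrac{2}{3}\sigma^2$;
the unique positive root of $1 - c + \tfrac{2}{3}c^2 = 1$ is $c =
\tfrac{3}{2}$, which restores the variance exactly.
`solve_variance_coefficient()` returns both the closed form and a numeric
root of the same moment equation so the derivation is self-verifying. A
useful side effect (verified in the test suite by Monte Carlo): the same
coefficient also preserves the third central moment, since
$E[(1-c\alpha)^3 + (c\alpha)^3] = 1$ at $c = \tfrac32$, so modified SMOTE
preserves skewness as well. The smoothed bootstrap preserves the mean and
inflates variance by exactly $h^2$.

### Out-of-range draws

Because modified SMOTE extrapolates, a synthetic interval can occasionally
fall below 0 or above 300 ms. The default (`bounds_policy = "none"`) keeps
such draws: clamping or redrawing would break the variance identity that is
the method's point. A `"redraw"` policy (resample until inside $(0, 300]$,
with redraw counts reported) is available for users who need physical
support, at the documented cost of biasing the moments. For the same reason
the strict-positivity invariant of a cohort is enforced for measured series
only.

## The generation protocol and rate semantics

Synthetic series are generated per record: each synthetic interval uses an
anchor drawn uniformly from the source series, and the synthetic series has
exactly the length of its source. The neighbor pool defaults to the source
record's own series; a pooled-minority mode is available behind
`neighbor_pool = "minority"`. An augmentation rate of $r\%$ adds $r/100$
synthetic series per original minority record, so 5 records at 200% add 10
series and 800% makes the minority dataset 9 times its original size (and,
at 41:5, exactly balances the classes). Synthetic series are unordered
samples; no serial autocorrelation of the source series is imitated, which
is deliberate — every downstream feature is a set statistic.

## Validating augmented data

`validate_augmentation()` draws `n_replicates` (default 100) augmented
datasets per technique and compares each replicate's pooled minority data
(original plus synthetic intervals — that is what "the augmented dataset"
means here) to the original minority intervals by four criteria:

1. maximum pointwise difference of binned empirical CDFs (5 ms bins on a
   shared grid);
2. absolute differences of the three quartiles (type-7 linear-interpolation
   quantiles, the common default — quartile definitions differ, so this is
   pinned down deliberately);
3. the two-sample Kolmogorov–Smirnov test's asymptotic p-value read as a
   similarity score (the comparison is between two empirical samples, so
   the two-sample flavor is the faithful choice; ties are expected since
   bootstrap replicates reuse original points, and the asymptotic p remains
   the intended measure);
4. signed percent differences of mean, sample variance and sample skewness,
   with a flagged absolute-difference fallback when an original moment is
   numerically zero.

Replicate-averaged statistics are ranked 1–3 across the three techniques
per criterion (smallest difference best, largest KS p best; ties share the
better rank).

Two of the six rank rows deserve a caveat that the package's own tests
respect. All three samplers are mean-unbiased by construction, so the mean
criterion compares three Monte-Carlo zeros and its ranking is noise.
Similarly, under per-record generation most of the pooled minority spread
comes from between-record differences, which all techniques preserve, so
the quartile criterion carries little signal about the within-record
variance correction. The regression test of the battery therefore asserts
stable behaviour — modified SMOTE never worst — on the CDF, KS, variance
and skewness criteria, where the samplers genuinely differ.

## Features

Ten descriptive statistics per series, in four groups: central tendency
(mean, median, mode), dispersion (standard deviation, variance), shape
(skewness, kurtosis) and length (maximum, minimum, sum). Estimator choices,
made explicit because the statistics' names alone underdetermine them:
sample ($n-1$) variance; adjusted Fisher–Pearson sample skewness; Pearson
(non-excess) kurtosis $m_4/m_2^2$; mode of continuous data as the most
frequent 1 ms-rounded value with ties broken toward the smallest. A
constant series reports zero shape statistics with a `degenerate` flag
rather than failing, so degenerate synthetic series stay usable.

## Feature selection

The filter method is the two-sided Wilcoxon rank-sum test per feature
(exact enumeration when both groups have at most 10 samples and no ties).
The wrapper method evaluates **all** $2^p - 1$ feature subsets (1023 for
$p = 10$) by cross-validated accuracy; at each combination length the
members of the best subset are credited 1, and a feature's score is its
credit divided by $p$, so scores lie on $\{0, 1/p, \dots, 1\}$. Ties for
the best subset go to the lexicographically first subset and are counted;
a subset on which the classifier fails scores accuracy 0 with a warning
rather than vanishing. The wrapper's internal evaluation is stratified
5-fold cross-validated accuracy with a fixed seed — the choice is recorded
here precisely because resubstitution would have been an equally plausible
reading. The combined relevance rule: a feature is relevant when its
wrapper score reaches 0.8 for a majority of classifiers, ordered by mean
score then filter p.

## Classifiers, folds and metrics

Three linear classifiers with fixed, logged settings: LDA with pooled
covariance; logistic regression with no regularization and a 0.5 threshold;
linear-kernel SVM with unit cost. Features are standardized per training
fold. Nonlinear classifiers are out of scope — with this little data they
mostly measure overfitting.

Cross-validation is stratified and **grouped**: a synthetic series is
always folded with the record it was generated from, so a record can never
lend synthetic copies of itself to the training side of its own test fold.
An ungrouped mode exists for sensitivity analysis only. MAFL is the
positive class everywhere: sensitivity is MAFL recall, specificity is FAFL
recall — the metric the imbalance destroys and the augmentation is meant to
rescue.

## Selecting the augmentation rate

For each rate in 100%–800%, the maximum cross-validated specificity over
all subsets of each combination length forms a curve over lengths. The
chosen rate minimises the Euclidean distance between its curve and the
pointwise average curve across rates; ties resolve to the smallest rate,
preferring the minimum synthetic ratio. Euclidean distance is a pinned
choice ("overall distance" admits alternatives).

## The synthetic cohort generator

Because the clinical recordings are not redistributable, the package ships
a generator that emulates the cohort structure the pipeline assumes, and it
is the substrate of every end-to-end test:

* 5 FAFL and 41 MAFL records by default; series lengths uniform on 40–120
  intervals;
* per-record base cycle lengths from class-level distributions with means
  230 ms (FAFL) and 248.10 ms (MAFL) and between-record SDs 22.36 and
  39.38 ms. These are read as record-level tachycardia cycle-length
  parameters, not pooled interval moments. Base cycles are drawn from a
  truncated normal on $(0, 300]$ whose location is solved numerically so
  the *truncated* mean equals the nominal class mean — naive rejection
  would bias the realised MAFL mean by about $-7$ ms and the generator
  could not recover its own parameters;
* intervals are the base cycle plus zero-mean Gaussian within-record
  jitter, rejection-sampled into $(0, 300]$ so the interval filter is a
  no-op on generated data;
* the jitter SD is itself random across records, Gamma-distributed with
  class means 12 ms (FAFL) and 3 ms (MAFL) and shape 1. The class means
  encode the core hypothesis (focal series more variable); the
  heterogeneity encodes the clinical reality that the two mechanisms'
  dispersion statistics overlap rather than separating cleanly — with a
  fixed per-class jitter the variance feature alone would classify the
  cohort perfectly and the imbalance problem the package exists for would
  not manifest. Shape 1 places the generator in the regime where
  unaugmented specificity is poor but recoverable.

What the generator does **not** emulate: serial correlation within a series
(focal path wander), non-Gaussian interval noise, inter-lead effects, or
any biophysical propagation model. Tests passing on this cohort show that
the pipeline's logic and contracts hold under the assumed statistical
structure; they are not evidence about clinical discrimination performance,
and the headline clinical numbers of the motivating study are deliberately
not asserted anywhere in the package.

## Numerical choices and problem sizes

Randomness is controlled by explicit seeds throughout; one master seed is
expanded into per-stage sub-streams so any stage can be reproduced in
isolation, and identical configurations produce byte-identical output
bundles. The variance-coefficient root is found to $10^{-15}$ tolerance and
agrees with the closed form to $10^{-12}$ or better. Sampler moment
contracts are exercised at $10^5$ Monte-Carlo draws; the validation battery
at 100 replicates; parameter recovery at 200 records per class; the
imbalance-regularisation trend over 20 replicate cohorts — sizes chosen so
each check is decisive at desk scale.

## Known limitations

* The wrapper is exhaustive by design and is guarded at $p \le 20$; it is
  not a scalable feature selector.
* The per-fold specificity of a 5-fold split of a 5-record minority class
  rests on one original FAFL record per fold; per-fold metrics are
  correspondingly coarse, which is inherent to the cohort size, not the
  implementation.
* The KS p-value is used as a similarity score, not as a calibrated test
  (replicates reuse the original sample, so independence assumptions do
  not hold); rankings built on it are comparative only.
* `peaks_to_intervals()` is deliberate plumbing: P-wave detection,
  T-wave-overlap handling and lead selection are upstream of this package.
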