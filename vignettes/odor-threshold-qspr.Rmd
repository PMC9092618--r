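---
title: "Methods: odor-threshold QSPR with GFA variable selection and PLS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: odor-threshold QSPR with GFA variable selection and PLS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aromaQSPR)
```

## The model

An odor threshold (OT) is the lowest concentration at which a trained
sensory panel reliably detects a compound; potent odorants have low
thresholds. The response modeled here is log10(OT in nmol): thresholds span
many orders of magnitude and panel variability is roughly multiplicative, so
the decimal log is the natural scale (a printed span such as −0.58 to 7.32
covers eight orders of magnitude in nmol). The predictors are numeric
molecular descriptors from any source; descriptor *computation* is outside
the package's scope.

The final regression is a single-response PLS model

$$\widehat{\log OT} = b_0 + \sum_j b_j z_j,$$

where the $z_j$ are the final pool's columns: raw descriptors and/or
truncated spline basis terms $\langle a - x\rangle = \max(0, a - x)$ whose
knot $a$ switches the descriptor's effect off above $a$. Splines let an
essentially monotone panel response saturate — e.g. molecular weight
raising thresholds only below some cutoff — while keeping the model linear
in its coefficients.

## Stage-by-stage assumptions and parameters

**Curation.** Literature thresholds for the same compound from different
sources are compared on the log scale. The tolerated spread `delta_max`
defaults to 1.0 log-unit: within-lab panel reproducibility is commonly a
factor of a few, so one order of magnitude separates "replication scatter"
from genuinely discordant protocols. Concordant sources are averaged *on
the log scale* (the response's scale — the geometric mean of raw
thresholds); discordant compounds are removed rather than adjudicated.
Both choices are configuration, not hard-coded.

**Pre-filtering.** Columns are removed in a fixed order: any missing value;
SD < 10⁻⁴ (constant and near-constant descriptors carry no information and
break autoscaling); then for every pair with |Pearson r| ≥ 0.95 the
*later* column in file order is dropped. Which member of a collinear pair
survives is arbitrary in principle; keeping the earlier column is a
deterministic, logged convention. The filter is idempotent.

**Rational division.** Compounds are clustered in autoscaled descriptor
space with k-medoid (default k = 6), implemented as canonical PAM: greedy
BUILD initialization, then steepest-descent SWAP passes whose total cost is
asserted non-increasing. Ties are broken by row order, so the clustering is
deterministic; a seed argument exists only for the optional randomized
tie-break. Within each cluster, compounds are ranked by distance from the
medoid and every `round(1/fraction)`-th compound (default: every 4th,
fraction 0.25) is assigned to the test set. This systematic pick spreads
the test set across each cluster's density profile, is exactly
reproducible, and leaves the medoid — the cluster's most central compound —
in training. Singleton clusters contribute no test compound. The exact
test-set size therefore depends on the cluster size profile: with 85
compounds in six clusters it lands near, but not always exactly at,
the 64/21 split that an exact 25% draw would give.

**GFA.** The genetic search evolves term lists, not coefficient vectors:
every genome is refitted by least squares whenever it changes. Fitness is
Friedman's lack of fit, LOF = LSE/(1 − (c + d·p)/M)², with c the number of
basis terms, p all fitted parameters *including spline knots*, M the
training-set size, and smoothness d (default 1.00) trading error against
complexity; models too large for their sample score +∞. The published
account of the original software names the score but not the formula; the
Friedman/Rogers convention above is the standard one. Search operators
follow the classical description: size-2 tournament parent selection,
prefix/suffix crossover with duplicate-term removal, and a mutation menu
(add, delete, replace-descriptor, resample-knot, toggle linear↔spline)
applied with probability 0.5; the worst population member is replaced each
iteration, so the best LOF never increases. Spline knots are restricted to
observed training values of the descriptor, keeping the search space finite
and every knot interpretable as "the value of compound X". Defaults mirror
the study settings (5000 iterations, initial length 4, no length cap);
population size is unpublished and defaults to 100. Whether linear and
spline terms competed in one population or separate runs is also
unpublished; `term_kinds` supports both (`"mixed"` default).

**Best subset.** The descriptors (and intact spline terms, as fixed
transformed columns) pooled from the top five GFA equations are searched
exhaustively: all C(p, 6) subsets are fitted by OLS on the training rows and
ranked by the MAE-based class (below), then MAE, on a validation set. The
study ranked on its held-out test set; that choice is kept as the default
(`subset_validation = "test"`) for fidelity, with an `"internal"` option
that carves a quarter of the training set instead, since ranking on the
final test set lets external information leak into model selection. Ties
are broken by lexicographic descriptor names. The compiled kernel
precomputes Gram-matrix blocks once, so the C(32,6) = 906,192-fit search —
the intended scale ceiling, guarded by a 2·10⁶ cap — takes seconds.

**PLS.** Single-y NIPALS on autoscaled X and scaled, centered y; each
component is closed-form, so only degenerate input can fail. Coefficients
are back-transformed to the original descriptor scale via
$W(P^\top W)^{-1}q$; predictions from the coefficient form and the
projection form agree to 10⁻¹⁰ and are tested to. The latent-variable count
maximizes leave-one-out Q², with ties to the smaller count; every LOO fold
honestly recomputes all scaling parameters on its n−1 rows — re-using
full-data means and SDs systematically inflates Q². The pipeline caps the
latent-variable count at one below the number of model columns so a
residual X-space always exists for DModX.

**Validation battery.** External metrics use their standard definitions:
R²pred (test SSE against training-mean deviance), Q²F2 (against test-mean
deviance), Lin's CCC with n-denominator moments. The rm² family is computed
on [0,1] min–max-scaled vectors by default, following the metric's own
literature, with the raw-scale variant available (`scaled = FALSE`) because
the study does not state which was used; both are reported. Thresholds:
0.5 for Q², rm² (both sets) and R²pred/Q²F2; 0.750 for CCC; 0.2 cap for
Δrm². The Golbraikh–Tropsha checklist (r² > 0.6, origin-ratio < 0.1 in
either direction, slope k or k′ in (0.85, 1.15)) is evaluated on raw
vectors. The MAE-based classes drop the 5% largest absolute errors (count
rounded half up), then require MAE ≤ 0.1·range *and* MAE + 3·SD ≤ 0.2·range
for "good", and declare "bad" above 0.15/0.25; the constants follow the
criteria's source publication since the study reports only verdicts.
Y-randomization permutes y (default 100 times), refits at the chosen
latent-variable count, and regresses R² and Q² on |cor(y, y_perm)|
*including the unpermuted point at cor = 1*, as in the described plot; the
model passes when the intercepts satisfy R²int < 0.4 and Q²int < 0.05.
Note the failure mode this test targets: an overfitted chance correlation
keeps high R² under permutation, lifting R²int above 0.4.

**Applicability domain.** DModX_i is the row's X-residual SD after
projection onto the A components, normalized by the pooled training
residual SD s0 (so the weighted mean of DModX² is 1 by construction). The
critical limit is $\sqrt{F_{1-\alpha}(K-A,\,(N-A-1)(K-A))}$ at α = 0.01.
This is the published degrees-of-freedom convention; the commercial
software used in the original study applies a proprietary non-integer
correction, so its printed D-critical (2.222 at N = 64, K = 7, A = 3) sits
about 17% above this package's 1.843 — the limits are not numerically
interchangeable, though both flag on the order of 1% of well-behaved
training rows. Hotelling T² uses training-score variances and the
$\frac{A(N^2-1)}{N(N-A)}F_{0.95}(A, N-A)$ limit drawn as the score-plot
ellipse. PCA factor scores (for the low-vs-high-threshold separation plot)
are extracted from the correlation matrix and varimax-rotated
(Kaiser-normalized); scores rotate with the same orthogonal matrix, so
retained explained variance is preserved.

**Composite wines.** A wine's composite descriptor vector is the
(weighted-)mean of the *final model columns* — i.e. after spline
transformation — over its components; averaging raw descriptors and then
splining is not equivalent (the spline is convex) and is deliberately not
done. Because the model is linear in its final columns, a composite
prediction equals the weighted mean of the per-component predictions
exactly, and single-component wines reproduce individual predictions; both
identities are tested to 10⁻¹⁰. Weights default to uniform; whether the
original study weighted by concentration is not determinable from its main
text, so concentration weighting is supported but not assumed.

## The synthetic-data generator

`make_study()` emulates the statistical structure the pipeline must cope
with: descriptor blocks sharing a Gaussian latent factor (within-block
correlation ρ = 0.7 by default — strong enough to stress collinearity
handling but below the 0.95 filter), per-column location/scale variety,
plus constant, near-constant and missing-value columns for the prefilter,
and four extra compounds whose two "literature sources" disagree by more
than 1.5 log-units so curation has something to remove (89 → 85, the
curated study size). The response is intercept + two linear + two spline
terms (coefficients 2, −1.5, 1.5, −2; knots at the within-sample median so
the truncation is active for about half the compounds) plus Gaussian noise
of SD 0.6 log-units — a strong but realistically noisy QSPR signal
(signal-to-noise ≈ 6, fitted R² near 0.9). Concordant two-source compounds
average back to the exact planted response, so curation is exercised
without perturbing the truth.

What the generator does *not* emulate: real descriptor marginals (counts,
heavy tails, discreteness), physically meaningful inter-block structure,
and any relationship between descriptors and actual chemistry. Passing
tests therefore demonstrate that the *procedures* are correct and that the
chain recovers planted structure under realistic collinearity and noise —
not that any particular chemical conclusion transfers to real compounds.

One consequence of the correlated blocks is worth stating explicitly:
when a planted descriptor has siblings at ρ = 0.7, variable selection may
legitimately return a sibling instead — the information is interchangeable,
which is precisely why the workflow ends in PLS rather than MLR. Recovery
is therefore scored as "every planted signal represented by the descriptor
itself or a collinear carrier (|r| ≥ 0.6), with a majority by exact
identity", and the end-to-end check also verifies coefficient *signs* on
exact-identity columns (a linear column standing in for a planted spline
⟨a − x⟩ carries the flipped sign, since the spline decreases in x).

## Numerical conventions

* SDs use the n−1 denominator throughout, except the n-denominator moments
  inside Lin's CCC (its standard definition).
* Autoscaling tolerances: column means within 10⁻¹⁰ of 0, SDs within 10⁻¹⁰
  of 1; zero-SD columns are an error (impossible after prefilter).
* LOF returns +∞ when the complexity penalty denominator is ≤ 0.
* rm² involves $\sqrt{|r^2 - r_0^2|}$, which amplifies machine-epsilon
  differences to ~10⁻⁸; identity-based tests use a 10⁻⁶ tolerance there.
* All stochastic stages draw from a locally seeded RNG that restores the
  caller's random state; the pipeline derives per-stage child seeds from
  one master seed, so any stage can be reproduced in isolation.
* Exact ties: correlation-filter keeps the earlier column; subset ranking
  breaks (class, MAE) ties by sorted descriptor names; equal composite
  predictions rank by wine id; k-medoid candidate ties resolve to the
  lowest row index.

## Problem sizes used by the test suite

The suite exercises the same code paths as a full-scale run at sizes chosen
to keep the default check quick while preserving the statistics being
tested: GFA runs use populations of 40–100 and 150–500 iterations (the
5000-iteration default remains available and is purely a multiplier on the
same steady-state loop); recovery experiments use 10 seeds at n = 100 with
30 descriptors; the exhaustive-subset ceiling C(32,6) = 906,192 is run once
in full; Y-randomization checks use 25–50 permutations against the
100-permutation default; DModX/T² calibration uses n = 200
multivariate-normal rows.

## Known limitations

* The "modified" k-medoid variant and the population/selection scheme of
  the original commercial GFA tool are unpublished; canonical PAM and a
  size-2-tournament steady-state GA stand in, with all knobs exposed.
* The DModX critical limit follows the published F convention and is *not*
  numerically equal to the commercial software's corrected D-critical (see
  above).
* Best-subset ranking on the held-out test set reproduces the study's
  procedure but is statistically contentious; use
  `subset_validation = "internal"` when external honesty of the final test
  statistics matters more than fidelity.
* Composite predictions assume linear blending on the model's descriptor
  columns; perceptual mixture interactions (synergy, masking) are out of
  scope, as are odor-activity-value calculations.
* Unit handling is deliberately minimal: thresholds must already be in
  nmol; no μg/L conversion via molecular weight is attempted.
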