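---
title: "Models and methods for Yes/No ensemble-perception analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for Yes/No ensemble-perception analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ensembleYN)
```

## The task and the two hypotheses

A memory display of 64 bars carries two "old" feature values from a
7-level ordinal series (orientations 0°–90° in 15° steps, or one hue
family's seven luminance levels), two steps apart, leaving one intervening
level — the mean. A probe then carries the mean (M), an old value (O), or a
new value outside the old range (N, 1–4 steps from the nearest old item),
and the observer answers Yes ("was present") or No.

Two process models predict the response probabilities:

* **Perceptual averaging.** The display is summarised by its mean; p(No)
  rises with the probe's ordinal distance *x* from the mean, modelled by
  the three-parameter log-logistic

  $$p(\mathrm{No}) = a + \frac{1-a}{1 + e^{b - c x}},$$

  where $a \in [0,1]$ is the floor rejection rate, $b$ the location and
  $c \ge 0$ the slope. p(Yes) is defined as its complement $1 - p(\mathrm{No})$.
  (Two sign conventions circulate for the Yes-scale form of this function,
  and they are not mutual complements; we fix the p(No) form as
  authoritative and define p(Yes) as its exact complement, which keeps the
  pair algebraically consistent.)

* **Similarity.** The probe is confused independently with each old item
  with probability $g(d)$, a non-increasing kernel of the ordinal distance
  $d$ to that item, so $p(\mathrm{No}) = (1-g(d_1))(1-g(d_2))$. Because the
  two N1 probes are exactly as far from an old item as the M probe, the
  model yields the point prediction
  $p(\mathrm{No}|M) = p(\mathrm{No}|N_{1A}) \cdot p(\mathrm{No}|N_{1B})$.
  An observed p(No|M) *below* that product is evidence for averaging; note
  that a full trial-level similarity observer itself produces
  $p(\mathrm{No}|M) \le p(\mathrm{No}|N_1)$ (the M probe risks confusion
  with *both* old items), so the product prediction — not the raw M/N1
  comparison — is the discriminating statistic.

## Synthetic observers

`observer_averaging()` defaults to $a = 0.2034$, $b = 3.8528$,
$c = 1.8718$, the unique log-logistic through p(No) = 0.22/0.30/0.58 at
distances 0/1/2 — the marginal means the orientation task is designed
around; the curve extends monotonically to 0.883/0.980/0.997 at distances
3–5. `observer_similarity()` defaults to the kernel
$g = (0.80, 0.45, 0.15, 0.05, 0)$, chosen once as a plausible monotone
confusion gradient whose implied category probabilities (O ≈ 0.17,
M ≈ 0.30, N1 ≈ 0.52, N2 ≈ 0.85) bracket the colour-task marginal means.

On factorial designs (experiments 3 and 4) the response probability is the
mixture $(1-\lambda)\,p_\text{relevant} + \lambda\,p_\text{irrelevant}$,
with $\lambda = 0.15$ by default: the factorial analyses are built to
detect irrelevant-dimension main effects roughly an order of magnitude
smaller than the relevant ones, and a 0.15 weight produces that regime
while leaving the relevant effect dominant. The irrelevant term uses its own
observer (by default the same rule); the pipeline default follows the
empirical pattern — averaging on orientation, similarity on luminance —
with the opposite rule on the irrelevant dimension.

What the generator emulates: the 7-step series and families (tilt
direction; green/blue, from the packaged colorimetry table), old pairs two
steps apart with uniform position, probe allocation at the designed counts
(240 O / 120 M / 120 N in experiments 1–2; the 80/40 factorial cells in
experiments 3–4), practice trials flagged for exclusion, binomial
responses, and display layouts honouring the central exclusion disc and
the 32/32 (and 16-per-combination) value assignments. What it does not
emulate: sequential effects, lapses or response bias drift, perceptual
noise on the feature continuum (confusion operates on ordinal steps),
display-position effects, and reaction times. Passing tests therefore show
that the *analysis* behaves correctly on data with the assumed structure,
not that real observers satisfy that structure.

## Classificatory schemes and fitting

`condition_table()` casts each participant's non-practice trials as exact
proportions of No responses per category. Under `from_mean` the predictor
is distance from the mean (M at 0, O at 1, N at 2–5); under `from_old`,
distance from the nearest old item (O at 0, M and N1 both at 1, N2–N4 at
2–4). Empty categories are reported as absent, never imputed.

`fit_psychometric()` minimises count-weighted least squares (weights
normalised to mean 1, so RSS is on the unweighted scale) over
$(a, b, c)$ with bounds $a \in [0,1]$, $b \in [-20,20]$, $c \in [0,20]$.
Optimisation is deterministic: a fixed 4×4×4 grid over
$a \in [0, 0.6]$, $b \in [-2, 6]$, $c \in [0.1, 4]$ is screened on RSS and
bounded L-BFGS-B runs from the three best starts; repeated fits of the
same table are identical. Noiseless inputs are recovered to better than
1e-4; a constant-p(No) table drives $c$ to its boundary and is flagged
degenerate rather than dropped. Fits use category proportions by default
(matching how the data are plotted and reported); `bic_binomial()` offers
a trial-level binomial-likelihood criterion as an alternative.

**BIC.** The default is the Gaussian least-squares form
$n \ln(\mathrm{RSS}/n) + k \ln n$ with $k = 3$ and $n$ the scheme's own
number of fitted points. The two schemes have unequal $n$ (6 vs 5 when M
and N1 are pooled), which mildly advantages whichever scheme has smaller
per-point RSS; this is documented rather than corrected, since no single convention is
canonical for comparing fits over differently sized category sets.

**M/N1 pooling — the one place the default depends on the question.** For
*descriptive* fits and the scheme comparison we pool M with N1 at $x = 1$
in the from-old scheme (the conventional "N1 & Mean" category, reflecting
that both sit one step from the nearest old item). Pooling is,
however, lossy in a specific way: it averages away the M-vs-N1 contrast,
which is precisely the feature that separates the two generating rules.
On averaging-generated data the pooled from-old view is a smooth 5-point
curve that fits about as well as the averaging view, so BIC *selection*
between schemes would be one-sided. The power/model-selection machinery
(`run_power()`) therefore keeps M and N1 as separate points at the same
distance by default (`pool_m_n1 = FALSE`), which restores two-sided
discriminability; both behaviours are configurable in both places.

## Similarity prediction and exclusions

`similarity_prediction()` estimates the two product factors
side-specifically (below-/above-range N1 trials) when both sides have at
least `n_min = 5` trials, else falls back to the squared pooled N1
proportion; boundary old pairs put all four N candidates on one side, so
small sessions can starve a side. Both policies are available because either reading of "estimate the
factors from the N1 probes" is defensible.

`exclude_participants()` removes participants at (default, `p_no <= 0.5`)
or strictly worse than (`strict = TRUE`) chance on their largest
distance-from-mean N category — an observer who cannot reject probes five
steps from the mean is not doing the task. Threshold and strictness are
configurable; every decision is logged with the offending value.

## Inference conventions

* Paired t-tests via `stats::t.test`, two-sided; Cohen's d for paired data
  is mean difference over the SD of differences, so $d = |t|/\sqrt{n}$.
* `jzs_bf_paired()` computes the default-prior (JZS) Bayes factor by
  adaptive quadrature over the Zellner–Siow mixture; the prior scale
  defaults to $r = \sqrt{2}/2$ and is configurable (and echoed in output)
  so results can be matched against other default-prior choices.
* Repeated-measures ANOVAs use `stats::aov` with `Error()` strata: each
  effect is tested against its own participant-interaction error term, F
  uncorrected for sphericity (reproducing the conventional df: (2, 46)
  style for one-way, (2, 2(n−1)) and (4, 4(n−1)) for the 3×3).
* Tukey post hocs refer $q = |\Delta|/\sqrt{\mathrm{MS}_e/m}$ to the
  studentized range with the factor's own error df; marginal means use
  $m = n \times$ (levels of the other factor) scores per mean, simple
  effects use the interaction error term with $m = n$. Chains such as
  `N1 > O > M` join adjacent ordered means with `>` when the pairwise
  adjusted p is below 0.05.

## Power simulation

`run_power()` reproduces the registered sample-size logic: per replicate,
binomial No counts (12 trials per condition by default) are drawn for each
simulated participant over the six distance-from-mean categories; both
schemes are fitted per participant; the scheme with the lower group-average
BIC wins; power is the fraction of 500 replicates won by the generating
scheme, with Clopper–Pearson Monte-Carlo intervals (a single-replicate run
reports the degenerate interval [0, 1]). BIC ties count against the
generating scheme. Group sizes 2–10 share each replicate's participants
(size $g$ uses the first $g$), so the power curve is evaluated on paired
data — the form in which monotonicity in group size is a meaningful
property. The original pilot probabilities were never published, so two
presets anchor the generating model to the reported marginal means
(averaging: 0.22/0.30/0.58 extended along the anchored log-logistic;
similarity: 0.24/0.46/0.70/0.85/0.92 by distance from old); custom
probability maps are accepted.

## Numerical choices and degenerate inputs

* One root seed drives named sub-streams (design / layout / response /
  power replicate), so the trial sequence is invariant to the observer
  model and any stage can be reproduced in isolation.
* `exp()` overflow in the log-logistic saturates harmlessly to the
  asymptotes; probabilities outside [0, 1] from a user-supplied kernel are
  an error, not a clamp.
* A perfect fit (RSS = 0) yields BIC −∞ with a message — it can occur
  with fabricated noiseless tables but not with binomial data.
* Zero-variance difference vectors: identically zero differences give
  t = 0, p = 1; constant non-zero differences are an error.
* An effect whose sum of squares is numerically zero relative to the
  response's total variation reports F = 0, p = 1 (avoiding 0/0 noise when
  the error stratum is also empty).

## Problem sizes used by the test suite

The suite exercises the pipeline at the scale of the designs themselves:
sessions of 480 experimental trials; 21 pooled sessions (>10,000 trials)
for the similarity-estimator consistency check; 24 simulated participants
for the averaging-signature test; 100 sessions for parameter recovery; 500
synthetic participants for BIC scheme recovery; 500 bootstrap replicates
for the power curve and for the type-I-error check of the paired test.

A note on parameter recovery at this scale: with six category proportions
and a saturating upper tail carried by few trials, the location and slope
of the log-logistic trade off (per-session SD of $\hat b$ is on the order
of 1.5), and their medians across 100 sessions of 480 trials carry a
finite-sample bias of a few hundredths to ~0.1 — visible in the recovery
test, and inherent to the design rather than to the optimiser (noiseless
recovery is exact) or the objective (the binomial-likelihood variant shows
the same order).

## Known limitations

* The analysis operates on ordinal step distances; it does not model the
  metric spacing of the luminance series (which is not equidistant in Y).
* The similarity observer assumes independent confusions with the two old
  items; correlated confusion processes are out of scope.
* No hierarchical pooling across participants: every fit is
  per-participant by design.
* The column-mapping reader adapts flat trial-level CSVs; raw jsPsych
  output must be flattened upstream.
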