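---
title: "Class-balanced active learning: model, cost theory and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Class-balanced active learning: model, cost theory and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbal)
```

## The problem

Training a binary classifier to find a rare target class — cancerous
regions in digitized tissue being the motivating case — runs into two
coupled inefficiencies. Random annotation wastes expert effort on samples
the classifier already handles, and at a ~4% target prevalence it fills
the training set with majority-class examples, biasing the decision
boundary. `cbal` couples a query-by-committee active learner with
explicit class-ratio control and, because balancing a rare class is
costly, a stochastic model that predicts that cost before any annotation
is spent.

## Model and procedure

**Committee and eligibility.** The learner keeps a committee of `m`
decision trees (rpart, unpruned, each fit on a bootstrap resample of the
labeled set). The fuzzy confidence `T(r)` of a sample is the fraction of
members voting for the minority class, taking values on the grid
`{0, 1/m, …, 1}`. A sample is *eligible* when `|T(r) − 0.5| ≤ τ`. Two
properties of this definition matter:

* the inequality is inclusive, so `τ = 0.5` admits the entire pool —
  including unanimous votes at 0 and 1 — and the strategy then provably
  degenerates to balanced random sampling (this exact equivalence is a
  tested invariant, not just an asymptotic claim);
* with an odd committee `τ = 0` can never be satisfied, which is why the
  default committee size is even.

**Quota-constrained annotation.** Each iteration draws eligible samples
uniformly without replacement and pays one oracle call per *distinct*
sample, ever. Samples whose class quota is already full are cached; later
iterations consume the cache before drawing. This makes the cost
accounting exact: total oracle calls always equal the bootstrap charges
plus the summed per-iteration costs `N_t`, and no sample is ever charged
twice. When the eligible set runs dry mid-iteration, the drawing falls
back to the whole unlabeled pool (on by default, logged in the audit
trail) — the worst case is therefore plain balanced random learning, not
failure.

**Cost model.** With minority-observation probability `p_t`, the number
of annotations to the `k̂₁`-th minority sample is negative-binomial.
`predict_annotations()` offers two inversions of the model at confidence
`P_Δ`:

* `"quantile"` (default): the smallest `N` with
  `P(≥ k̂₁ successes within N) ≥ P_Δ` — a cumulative statement, which is
  what "the quota is met within N annotations with confidence P_Δ"
  means, and the mode used for budgeting;
* `"as_printed"`: the `N` whose *pmf* value is closest to `P_Δ`
  (smallest-N tie-break). Matching a density to a confidence level is not
  a quantile and is retained only as a documented variant for
  reproducibility of the literal matching rule.

`predict_cost_curve()` iterates prediction and the update
`p_{t+1} = (k₁,t − k̂₁)/(k₁,t + k₂,t − N_t)` over a finite pool. Two
details are deliberate:

* the per-iteration prediction is floored at the batch size `k̂₁ + k̂₂`
  (an iteration can never need fewer annotations than batch slots when
  the cache is empty) and capped at the remaining pool;
* the modeled pool advance removes at most the available majority count,
  so degenerate settings (`p = 1`, all-minority pools) stay consistent
  instead of producing probabilities above 1.

Because the `P_Δ`-quantile is an upper percentile, it is the wrong
quantity to compare against *trial-averaged* observed costs; for that the
curve exposes `statistic = "mean"`, the negative-binomial expectation
`k̂₁ / p_t`. At `p = 0.04` the expectation is 25 annotations per balanced
(1, 1) pair while the 95% quantile is 74 — conflating the two would make
any fidelity assessment meaningless.

**Evaluation.** Training sets are judged by a boosted-tree scorer
(xgboost, logistic objective) — deliberately a different model family
from the committee, so the selector does not grade its own homework. The
ROC is built by sweeping the decision threshold over all distinct scores
plus {0, 1} with the strict rule `label 1 ⇔ score > θ`; AUC is the
trapezoidal area, which equals the Mann–Whitney pairwise statistic with
ties credited ½ (a tested identity). The operating point maximizes
Youden's J, ties broken toward the lower threshold; the
closest-to-(0,1) convention would be an equally defensible choice, and
accuracy is reported at whichever threshold is selected, so the
convention is documented rather than hidden.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `tau` | 0.25 | eligibility half-width around 0.5; 0.25 admits samples where ≥ a quarter of members dissent |
| `m` | 10 | committee size; even, so exact 0.5 disagreement is attainable; 10 keeps vote granularity at 0.1 |
| `k1_hat`, `k2_hat` | 1, 1 | per-iteration class quotas; (1, 1) retrains the committee after every balanced pair, maximizing the information behind each selection |
| `P_Δ` | 0.95 | model confidence for quantile cost predictions; a conventional planning percentile, configurable |
| `delta` | 0.02 | stopping threshold on `|A_t − A_{t−1}|`, applied post hoc to recorded traces |
| `bootstrap_size` | 10 | initial random training set; drawing appends (and charges) until both classes appear, the smallest set that lets bagging function |
| `levels`, `distance` | 64, 1 | co-occurrence quantization and offset; the standard convention for patch-scale texture |

The initial probability estimate `p₀` is taken from the bootstrap set's
empirical minority fraction (`p0_hat` on the run object) in deployment;
simulation harnesses may set it explicitly.

## The synthetic generators: what they do and do not show

`make_feature_pool()` draws both classes from unit-covariance Gaussians
whose means differ by `class_separation` along a random direction, with a
deterministic (rounded, not binomial) minority count. This is the
simplest model with a tunable hard-boundary region — which is what active
learning feeds on — and it makes class-count invariants exactly testable.
The default study condition used throughout the tests is a 12,588-sample
pool at 4% minority prevalence and separation 2.0, split 11,242 train /
1,346 test.

`make_texture_dataset()` renders minority patches as an oriented
sinusoidal grating (frequency 0.2 cycles/pixel, orientation π/4,
amplitude 0.35 on the unit intensity scale) over Gaussian noise
(sd 0.08), majority patches as pure noise at the same mean. The classes
therefore differ in second-order statistics by construction, which
guarantees Haralick/Gabor separability — useful for testing the feature
path, but a far cry from tissue appearance.

Passing tests on these generators demonstrate the *mechanics* —
eligibility semantics, quota exactness, cost conservation, cost-model
fidelity, ranking of strategies under a genuinely imbalanced pool. They
do not certify performance on real histopathology: Gaussian pools have no
label noise, no feature correlation structure, no within-class
heterogeneity, and the synthetic textures are stationary. Absolute
accuracy/AUC values on real data will differ; the *relative* claims
(balanced active learning dominates unbalanced random learning at a fixed
added-sample budget; balancing cost grows like `k̂₁/p`) are the
transferable content.

## Numerical choices and degenerate inputs

* **First-order `std`** is the population standard deviation (divisor
  N), matching its definition as a per-window moment rather than a
  sample estimate.
* **Haralick features** use natural logarithms, `0·log 0 = 0`, a
  symmetric direction-averaged GLCM (the four normalized directional
  matrices averaged, so entries sum to 1 within 1e−12), and guarded
  definitions — correlation and the first information measure are 0 when
  the relevant variances or entropies vanish — so all 13 statistics are
  finite on constant, random and single-level patches. Sum variance is
  centered on the sum average.
* **Gabor kernels** are complex, DC-subtracted (exactly zero response to
  constants) and L2-normalized (responses comparable across frequencies —
  without this, wide low-frequency envelopes dominate every response).
  The envelope sd is tied to wavelength (`σ = 0.56/f`, ≈ one octave);
  support is truncated at 3σ and capped to fit the image, a necessary
  compromise for low frequencies on 30-pixel patches.
* **Eligibility** uses a 1e−12 slack on the inclusive inequality so the
  `τ = 0.5` limit is immune to floating-point representation of the vote
  grid.
* **Determinism**: every run expands one root seed into fixed-layout
  per-iteration streams (query, committee, evaluation, bootstrap). The
  query stream is allocated first, so strategies that do and do not train
  committees consume identical query randomness — this is what makes the
  CBAL(τ = 0.5) ≡ CBRL equivalence exact, sample for sample, rather than
  merely distributional.
* **rpart members** are fit with `xval = 0`: cross-validation would both
  waste time and consume RNG inside the committee.

## Open design points, resolved

* *"Information measure" and "contrast variance"* in the 5-feature
  Haralick subset are ambiguous names; the shipped 14-feature default
  uses the first information measure of correlation and contrast (with
  variance still available in the full 13-set). The selection is a named
  configuration, not a discovery claim.
* The 7 *informative Gabor filters* are likewise a named stand-in chosen
  to span frequencies (0.1, 0.2, 0.4) and all four axis/diagonal
  orientations at the middle frequency; any other subset can be passed as
  `selection`.
* *Pixel-wise then averaged*: first-order and Haralick features use one
  window equal to the region (the limiting case of a sliding window);
  Gabor responses are computed by full-image convolution and averaged
  over the region's pixels.
* *Surplus annotations*: cached per class and consumed before new draws —
  the cost-minimizing reading of "saved for future iterations" — with
  cache consumption logged separately (`source = "cache"`) so cost traces
  stay interpretable. Per-iteration `N_t` counts genuine oracle calls
  only.
* *Unbalanced active learning* annotates the first `K` randomly drawn
  eligible samples regardless of class, the natural unbalanced analogue
  of quota filling.

## Problem sizes in the shipped tests

Unit tests run on pools of 20–600 samples. The study-scale checks use the
full 11,242/1,346 split: cost-model fidelity averages 50 independent
balanced-querying replicates over 40 iterations, and the
strategy-ordering check compares CBAL and UBRL across 20 trials at the
80-added-sample budget, evaluating AUC at the final iteration. Monte
Carlo oracles use 10⁴–10⁵ replicates. These sizes were chosen so each
claim is tested at the prevalence and scale it is made for while the
whole suite stays comfortably rerunnable on a laptop.

## Known limitations

* Binary classification only; the multi-class generalization of both the
  quota mechanism and the cost model is out of scope.
* The cost model assumes draws are effectively with-replacement within an
  iteration (`p_t` fixed while drawing); at pool sizes in the hundreds
  this hypergeometric error is visible, which is why fidelity is claimed
  at the 10⁴-sample scale.
* In deployment the update's class counts are unobservable; the
  `running_estimate` mode substitutes `p_t`-proportional estimates, which
  propagates estimation error across iterations.
* The stopping criterion assumes accuracy rises roughly monotonically;
  on noisy evaluation sequences it can trigger early at a chance
  plateau.
* Committee confidences are vote fractions, not calibrated
  probabilities; `τ` is a rank-style margin, not a probability margin.
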