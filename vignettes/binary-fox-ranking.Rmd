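---
title: "Binary FOX wrapper feature selection and half-quadratic ensemble ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binary FOX wrapper feature selection and half-quadratic ensemble ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bfox)
```

## The problem

Medical-image classification pipelines frequently produce feature tables
that are far wider than they are tall: a few hundred ultrasound or
histopathology samples described by hundreds of transformer-derived
descriptors, usually compressed first by a nonlinear embedding. Wrapper
feature selection asks which small subset of those columns actually
supports a classifier, trading predictive performance against the size of
the retained feature space. Because the selectors in this family are
stochastic, any serious comparison of selector variants must rank
algorithms from *distributions* of outcomes, not single runs. `bfox`
implements both halves of that workflow:

1. **Selection** — binary variants of the FOX metaheuristic (eight S/V
   transfer-function binarizations) wrapped around a Gaussian Naive Bayes
   classifier with stratified cross-validation, minimizing a weighted
   multi-objective cost.
2. **Ranking** — A-TOPSIS and Hellinger-TOPSIS applied to per-variant
   (mean, SD) result tables, fused by robust half-quadratic rank
   aggregation with consensus and trust diagnostics.

## The selection model

A candidate subset is a bit mask $m \in \{0,1\}^d$ with at least one
active bit. Its fitness is the cost

$$
CF(m) = -\bigl(a\,\mathrm{Acc} + b\,F_\beta + c\,\mathrm{AUC}
        - d \cdot 100 \cdot \tfrac{\mathrm{CSF}}{\mathrm{FSD}}\bigr),
\qquad a+b+c+d = 1,
$$

with accuracy, $F_\beta$ and AUC-ROC on the percent scale, CSF the number
of selected features and FSD the total feature count. Lower cost is
better. Defaults: $a=b=c=d=0.25$ and $\beta = 2$ (recall weighted four
times precision, the usual choice when missed malignancies are costlier
than false alarms). The percent scale keeps the four terms commensurate;
the feature-fraction term is likewise multiplied by 100 so that a weight
of 0.25 prices one extra feature (out of, say, 30) at about 0.8 cost
units.

Metrics come from stratified $k$-fold cross-validation (default $k=5$)
of a Gaussian Naive Bayes classifier. Oversampling of the minority class
is applied *inside each training fold only* — validation folds are never
resampled, so no duplicated row ever crosses the train/validation
boundary. The classifier uses maximum-likelihood per-class variances with
a floor of $10^{-9}$ times the largest feature variance, which keeps
constant columns (common under aggressive masks) well-defined. AUC uses
the rank (Mann–Whitney) formulation with ties averaged.

## The FOX dynamics and their binarization

Each of `n_agents` foxes carries a continuous position
$x \in [-1, 1]^d$ and a binary position (the mask). Per iteration and
agent a phase variable $r \sim U(0,1)$ selects:

* **Exploitation** ($r \ge 0.5$): per-dimension sound travel times
  $t \sim U(0,1)^d$; the distance to the prey is half the best continuous
  position (the sound travels there and back); the jump is
  $\tfrac12 \, 9.81 \, (\bar t/2)^2$ and the new position is
  `distance * jump * c` with $c = 0.18$ with probability 0.82 and
  $c = 0.82$ otherwise.
* **Exploration** ($r < 0.5$): position = best position $\odot\,U(0,1)^d$
  times the minimum observed mean travel time times the decaying schedule
  $a = 2\,(1 - u/U)$ at iteration $u$ of $U$.

The continuous position is then binarized:

* **S family** (sigmoids with slopes 2, 1, 1/2, 1/3): each bit is drawn
  by comparing a uniform variate with $T(x)$. The default orientation
  (`as_printed`) activates a bit when $\mathrm{rand} \ge T(x)$, i.e. with
  probability $1 - T(x)$; the `conventional` switch restores the usual
  rule. Both are exposed because the two orientations produce genuinely
  different searches and the non-standard one is the package default for
  fidelity to the method being reproduced.
* **V family** ($|\mathrm{erf}(\tfrac{\sqrt\pi}{2}x)|$, $|\tanh x|$,
  $|x/\sqrt{1+x^2}|$, $|\tfrac2\pi\arctan(\tfrac\pi2 x)|$): each bit of
  the *previous* mask is complemented with probability $T(x)$ and kept
  otherwise. V3 uses $x^2$ under the radical so that the function is even
  and defined for all reals.

All-zero masks are repaired by switching on exactly one uniformly random
bit. Best-so-far tracking is elitist with first-found tie-breaking, so
every cost history is monotone non-increasing and reproducible from the
seed: the wrapper evaluation isolates the RNG stream and memoizes by
mask, so a cache hit cannot perturb the optimizer's trajectory.

### Known limitation: position collapse

Both update rules multiply the best continuous position by factors well
below one (jump $\approx 0.3$, $c \le 0.82$, and a decaying exploration
schedule), so whenever the incumbent improves, the continuous positions
contract toward the origin. At $x \approx 0$ the V-family transfer gives
$T \approx 0$ (masks freeze) while the S family gives $T \approx 0.5$
(masks resample essentially at random). The search therefore behaves like
an annealed random search: reliable on small feature spaces (it attains
the exhaustive-search optimum on 8-feature tables, and can never beat
it — a property the test suite asserts), but weak at concentrating on a
small planted subset in 30 or more dimensions. The planted-recovery
experiment in the acceptance suite documents this honestly rather than
altering the dynamics; users who need sparser solutions should raise the
feature-fraction weight $d$ or seed the binary layer with sparse masks.

## The synthetic generator

`generate_features()` emulates the statistical skeleton the wrapper
assumes: `n_informative` columns drawn from class-conditional
unit-variance Gaussians whose means differ by `effect_size` SD units,
the remaining columns standard Gaussian noise, and a minority fraction
implemented by direct rounded label counts (distributionally identical to
balanced generation followed by minority subsampling, while preserving
the requested sample count exactly). It deliberately does **not** emulate
the correlation structure, heavy tails or patch-level redundancy of real
transformer embeddings — passing tests therefore demonstrate correctness
of the machinery under a known signal, not clinical performance.
`generate_result_table()` supplies the ranking stack with (mean, SD)
tables drawn from per-cell Gaussians, one RNG sub-seed per alternative.

Default study conditions used by the test and acceptance suites: wrapper
sanity checks on $n = 300$, $d = 10$; the exhaustive-oracle comparison on
$n = 80$, $d = 8$ (255 masks); the planted-recovery experiment on
$n = 200$, $d = 30$ with 3 informative columns at effect 2.5, 30 agents
and 100 iterations over 10 seeds; the end-to-end benchmark at reduced
sizes (four variants, 15 agents, 30 iterations, 5 runs). These sizes were
chosen as the smallest at which each property is clearly expressed.

## The ranking stack

Per-variant multi-run statistics (means and SDs of accuracy, F2, AUC and
the selected-feature count over repeated runs) form an $L \times K$
decision matrix with two layers.

**A-TOPSIS** runs classical TOPSIS twice — on the mean layer with the
given criterion directions, and on the SD layer with every criterion
treated as a cost (smaller dispersion is better) — then stacks the two
closeness vectors into an $L \times 2$ benefit matrix combined by a final
TOPSIS pass with weights `(w_mean, w_sd)`, default (0.5, 0.5). Columns
are vector-normalized; when all alternatives coincide, closeness is
defined as 0.5 so that pure ties resolve by index.

**H-TOPSIS** treats each cell as a Gaussian $N(\mu_{ij}, \sigma_{ij})$.
The ideal cells per criterion are those of the alternative with the
best/worst mean; separations are unweighted sums of Hellinger distances

$$
D_H^2 = 1 - \sqrt{\tfrac{2\sigma_1\sigma_2}{\sigma_1^2+\sigma_2^2}}\,
\exp\!\Bigl(-\tfrac{(\mu_1-\mu_2)^2}{4(\sigma_1^2+\sigma_2^2)}\Bigr),
$$

and closeness is $d^-/(d^+ + d^-)$. The exponent uses the squared *mean
difference*; a `strict_printed` switch reproduces a variant with
$\mu_1^2 + \mu_2^2$ in its place for comparison only, since that form is
not a distance (it is nonzero between identical Gaussians).

**Half-quadratic aggregation** fuses the $N$ rank vectors $S^n$ by
minimizing $\tfrac12\sum_n h(\lVert S^n - S^*\rVert_2)$ with a Welsch
loss, via the multiplicative half-quadratic alternation
$\alpha_n = \exp(-\lVert S^n - S^*\rVert^2 / 2\sigma_h^2)$,
$S^* = \sum_n \alpha_n S^n / \sum_n \alpha_n$, initialized at the
elementwise mean. In adaptive mode $\sigma_h$ is the mean residual plus
$10^{-8}$; a fixed-$\sigma$ mode guarantees monotone descent of the
surrogate objective (asserted per iteration in the tests). Rankings are
aggregated on the raw $1..L$ rank scale, which is what makes the
half-integer aggregate scores of two-method ensembles exact midpoints —
for $N = 2$ the result is loss-independent by symmetry. Final ranks
order the aggregate ascending with ascending-index tie-break.

The **consensus index** is the Gaussian-kernel agreement
$C = \overline{q_{kn}}$ with
$q_{kn} = \exp(-(S^*_k - S^n_k)^2/2\sigma^2)$, and the **trust level**
is its weight-aware counterpart $T = \tfrac1K \sum_k \sum_n w_n q_{kn}$
with $w_n = \alpha_n / \sum_j \alpha_j$. With uniform weights $T = C$
identically — in particular for any two-method ensemble. The kernel SD
defaults to 1.0 on the rank scale (about one rank position of slack);
it is a reporting parameter, not a fitted quantity.

## Numerical and design choices

* **Weights $a..d$ and the CV split protocol** are configurable, not
  fitted: the defaults (equal weights; fitness = CV mean on the supplied
  table, held-out evaluation via `train_test_split()` at 0.2) are the
  package's documented reading of an under-specified protocol.
* **LLE** (`lle_embed()`) is the standard reconstruction-weight
  formulation: $k$-nearest neighbors, regularized local Gram solve
  (ridge $10^{-3}\,\mathrm{tr}(G)$), bottom non-constant eigenvectors of
  $(I-W)^\top(I-W)$, and a deterministic sign convention (largest-
  magnitude entry positive). It requires $m < k < n$ and warns when $m$
  approaches $n$, where the embedding degrades. Note that LLE normalizes
  the embedding to unit covariance, so anisotropic manifolds are
  recovered only up to an affine rescaling.
* **Tie-breaks** everywhere are by ascending alternative index, which is
  what makes half-integer aggregate ties reproducible.
* **Determinism**: every stochastic entry point takes a seed and restores
  the caller's RNG state; multi-run experiments derive per-run seeds as
  `seed + 0..n_runs-1`.
* `inference_time` is recorded per evaluation but never enters the cost
  and is excluded from every assertion (it is hardware-dependent).

## What the tests do and do not show

The suite verifies: analytic anchor values of all eight transfer
functions and the Hellinger closed form (cross-checked against numerical
integration); hand-computed cost and F-measure cases; Naive Bayes and AUC
agreement with the independent `e1071` and `pROC` implementations;
exhaustive-search and grid-search oracle bounds; the exact reproduction
of three printed two-method rank-aggregation examples; and the
Monte-Carlo activation/flip rates of both binarization rules. It does
*not* demonstrate performance on real image-derived features, and the
planted-recovery experiment documents the search-power ceiling of the
as-specified dynamics discussed above.
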