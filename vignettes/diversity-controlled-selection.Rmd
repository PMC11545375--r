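---
title: "Diversity-controlled hybrid feature selection for coronary stenosis classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diversity-controlled hybrid feature selection for coronary stenosis classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stenoselect)
```

## The problem

Coronary stenosis — the narrowing of a coronary artery by plaque — is read
from X-ray angiograms, where contrast-filled vessels appear darker than the
surrounding tissue. A practical pipeline classifies small grayscale patches
(64×64 px) as positive or negative stenosis cases from hand-crafted
features: intensity statistics, gray-level co-occurrence (Haralick)
textures, and morphological descriptors measured on vessel-enhanced,
segmented versions of the patch. Such a feature bank easily grows to
hundreds of columns, most of them irrelevant or redundant, and the subset
that actually discriminates stenosis must be searched for: with $n$
features there are $2^n$ candidate subsets.

`stenoselect` implements a wrapper selector for this search: candidate
subsets are scored by training a support vector machine (SVM) on a training
split and measuring holdout accuracy, combined with a feature-reduction
reward. The optimizer is a hybrid metaheuristic — a Boltzmann Univariate
Marginal Distribution Algorithm (BUMDA) coupled with simulated annealing
(SA) refinement — plus an explicit *population-diversity control* whose
purpose is to delay the premature convergence that plagues
estimation-of-distribution algorithms on high-dimensional binary search
spaces.

## The fitness being maximized

An individual is a bit vector $x \in \{0,1\}^n$ marking selected features.
Its fitness is the weighted sum

$$f(x) = w_{acc}\,\mathrm{Acc}(x) + w_{fdr}\,\mathrm{FDR}(x),
\qquad w_{acc} = 0.90,\; w_{fdr} = 0.10,$$

where $\mathrm{Acc}(x)$ is the holdout (validation-split) accuracy of a
linear SVM trained on the selected columns and
$\mathrm{FDR}(x) = 1 - |x|/n$ is the *feature decreasing rate* (1 when
nothing is selected, 0 when everything is; not the false discovery rate).
The linear kernel is used inside the loop because it is cheap enough to be
called tens of thousands of times; a fine-tuned polynomial kernel
$(\langle x, x'\rangle / 2 + 0.3569)^5$ is applied once, after selection,
for the final test-split evaluation. Performance is reported with the
standard confusion-matrix metrics plus the Jaccard variant
$J_c = (TP+TN)\,/\,((A+P)-(TP+TN))$, where $A$ and $P$ are the numbers of
actual and predicted instances. Both equal the evaluation-set size in
ordinary use, which gives the useful identity $J_c = \mathrm{Acc}/(2 -
\mathrm{Acc})$; the implementation keeps $A$ and $P$ explicit so the
identity is testable. Degenerate denominators raise errors rather than
returning 0, so a silent misuse inside the optimizer loop is impossible.

## The optimizer

**BUMDA.** Each generation, individuals are weighted by
$W(X_j) = g(X_j) / \sum_j g(X_j)$ with $g$ the raw fitness, the
per-feature marginal is $\mu_i = \sum_j W(X_j) x_{ij}$, and the weighted
variance uses the companion weights $W'(X_j) = g(X_j)/(\sum_j g(X_j) + 1)$,
which sum to $G/(G+1)$ — kept exactly as the method defines them, with
$\nu$ serving as a convergence diagnostic. A truncation threshold
$\theta$ floors which members feed the model: at $t=1$ it is the worst
member's fitness; afterwards it moves to the fitness of the half-point
member when that does not fall below the previous $\theta$, and is
retained otherwise, so $\theta$ never decreases. On top of the $\theta$
floor, the selection rate (default 0.80) caps how many members are used,
taken in current population order. The next generation is sampled bit-wise
as Bernoulli($\mu_i$).

Three numerical choices matter here, all documented because the method is
usually stated for continuous domains:

* **Binary sampling law.** Bits are drawn independently from the
  Boltzmann-weighted marginal — the univariate-marginal reading of the
  algorithm applied to bit vectors.
* **Raw fitness as $g$.** Weights are proportional to the fitness itself,
  not $\exp(\beta f)$; a `boltzmann_beta` switch in `run_config()` enables
  the exponentiated form for users who want a sharper selection pressure.
* **Probability clamping.** $\mu_i$ is clamped to $[p_{\min}, 1-p_{\min}]$
  with $p_{\min} = 1/n$, so no feature can fixate to probability 0 or 1 —
  premature fixation is precisely the failure mode the diversity control
  targets, and the clamp keeps every subset reachable forever.
* **Repair.** A sampled individual with no set bit gets one uniformly
  random bit set; an empty mask is otherwise an invalid individual and
  scores fitness 0.

**Simulated annealing.** The temperature falls linearly from 1 to 0 in
constant steps of 0.001 (≈1000 iterations). The method's acceptance rule
is stated via the Boltzmann distribution; written as printed,
$\Delta E / T$ is not a probability, so the implementation uses the
standard Metropolis form $\min(1, \exp(\Delta E / T))$ for maximization —
improvements are always accepted, worsening moves with temperature-damped
probability. The neighborhood operator (unspecified in the source method)
flips each bit independently with probability $1/n$ with at least one flip
forced: expected moves of about one bit with nonzero reachability of every
state. `anneal()` returns the best-so-far solution, which guarantees the
refinement contract (output fitness ≥ input fitness) regardless of the
acceptance trajectory.

**The hybrid loop with diversity control.** Per generation:

1. evaluate the population (memoized wrapper fitness);
2. SA-refine the current **best** and the current **worst** member. The
   population receives each refinement's *annealed endpoint* (the last
   accepted state), while the refinement's *best-so-far* solution feeds
   the global best — so the population stays an honest sample of what
   annealing produces, and no discovery is ever lost;
3. update the global best (gbest) only on *strictly* greater fitness;
4. **diversity rule:** the refined worst counts as "the best SA-refined
   individual" when its annealed endpoint reaches at least the refined
   best's endpoint; on those generations the population is sorted
   worst-first, otherwise best-first. When inverted, the selection-rate
   window feeds the marginal model with low-fitness members — the
   deliberate exploration injection;
5. build the marginal model from the rate-windowed, θ-floored selection
   and sample the next generation.

Two semantics here were chosen for mechanism coherence and deserve
emphasis. First, replacement by the annealed endpoint (rather than the
best-so-far) puts the two refined individuals on an equal footing: the
best-so-far of a refinement started from the incumbent best can never
fall below its start, so under best-so-far replacement the worst member
could essentially never outrank it and the diversity rule would go
silent; endpoint replacement restores the regime in which the rule fires
on a meaningful fraction of generations ("some new populations are
generated by considering the worst individuals") while gbest still
collects every best-so-far. Second, the selection feeding the marginal
model is *positional*: the candidate window is the first
`ceiling(selection_rate * npop)` members in the current (possibly
inverted) order, floored by θ. If the θ filter were applied to fitnesses
independently of order, the selected *set* would be identical whichever
way the population is sorted and the inversion could never influence the
model. Inversions are logged per generation (`sort_inverted`) so the
behavior is auditable. The gbest is kept outside the population — never
re-injected — so elitism exists only in reporting. Ties in sorting are
broken by population index (stable sort) for reproducibility.

The full SA schedule inside every generation would cost ≈2000 extra
fitness evaluations per generation. `sa_refine_iters` (default 25) runs
the *tail* of the configured schedule — same constant step, starting at
`sa_t_end + sa_step * sa_refine_iters` — i.e. the cold phase in which
annealing actually climbs; the full schedule is available by setting it
to `(sa_t0 - sa_t_end)/sa_step`.

**Baselines.** `run_baseline()` provides an elitist generational GA
(parents drawn from the best `selection_rate` fraction, one-point
crossover, per-bit mutation $1/n$ — the conventional stand-in, since the
reference GA's operators are not fully specified), a single-solution SA
over the full schedule, plain BUMDA (no refinement, no diversity), and
the hybrid without diversity, all with the same logging contract:
per-generation best/worst/gbest fitness, sort-inversion flag, and
per-feature selection counts, from which `selection_frequencies()` and
`best_generation_stats()` reproduce the frequency-uniformity and
convergence-delay analyses.

## The feature bank

`extract_feature_vector()` produces a 228-feature catalog: 6 intensity
statistics of the raw patch, 14 Haralick features, and per enhancement
method (8 of them) the 6 intensity statistics of the response plus 20
morphological features of its segmentation. The exact 473-feature catalog
of the reference pipeline is defined in an external report and is out of
scope; this catalog covers every feature family by name (vessel lengths,
segment counts, compactness, circularity, elongatedness, gray-level and
gradient coefficients of variation, per-section segment-length
dispersion) with stable, human-readable names such as
`"Mean Vessel Length (Frangi)"`.

**Filters.** Vessels are darker than background, so ridge filters operate
on the inverted patch rescaled to 0..255 (keeping the Hessian threshold
$\beta = 15$ on its conventional scale). The bank comprises Frangi
vesselness and a Salem-style Hessian variant (σ from 1 to 12 px in steps
of 0.5, α = 0.5, β = 15; the Salem filter is implemented as an
eigenvalue-magnitude-difference vesselness sharing those parameters — a
compatible stand-in, since the original formulation is defined in a
reference we do not reproduce), single- and multi-scale Gabor banks,
oriented zero-mean line kernels (lengths 1–15 px, 12 orientations),
single- and multi-scale Gaussian matched filters, and the morphological
top-hat with a disk structuring element of size 19. Parameter symbols
follow the matched-filter literature and are interpreted as: Gabor `K` =
orientations over 180°, `T` = vessel thickness in px, `L` = kernel
elongation, `I` = number of scales; Gaussian matched filter `T` = angular
step in degrees (15° ⇒ 12 orientations), `L` = kernel length 13 px, σ as
given. The multi-scale Gabor bank reuses the single-scale elongation.
Multi-scale and multi-orientation methods take the per-pixel maximum over
their bank. All kernels of a bank are applied through one shared FFT of
the replicate-padded image with precomputed kernel FFTs — the difference
between ~3 s and ~0.7 s per patch for the ~480-kernel default bank.

**Segmentation and morphology.** Responses are thresholded by Otsu's
method. Per connected component ("arterial section"): area, boundary-chain
perimeter (diagonal steps count √2 — the digital-perimeter choice
dominates compactness values, so it is fixed and documented), compactness
$C = P^2/A$, circularity $R_c = 4\pi A/P^2$ computed as $4\pi/C$ so the
identity $C \cdot R_c = 4\pi$ holds exactly, and elongatedness from the
minimum-area *rotated* rectangle (rotating calipers over the convex hull
of pixel corners, so a 10×2 block measures exactly 5). The skeleton
(Zhang–Suen thinning) yields per-section vessel lengths and branch
segments split at end/branch points; segment lengths are pixel counts.
Empty masks yield the sentinel −1 for every morphological feature with a
warning — all regular values are non-negative, so the sentinel is
unambiguous and never a silent zero.

## Synthetic data: what it emulates and what it does not

Two generators make the package testable end to end without the external
angiogram database.

`make_feature_dataset()` plants a Gaussian class shift: informative
features are $N(\pm e/2, 1)$ by class, optional redundant copies add
correlated columns, the rest are pure noise. The model is chosen for
analytic tractability — the Bayes error of $k$ independent shifted
features is $\Phi(-e\sqrt{k}/2)$, which bounds what any selector can
achieve — not for realism.

`make_vessel_patch()` draws a dark tube of configurable width along a
quadratic arc on a brighter background with Gaussian noise; a positive
`narrowing` fraction reduces the width at mid-arc with a smooth profile,
emulating a stenotic lesion. `make_patch_bank()` mirrors the balanced
database design (e.g. 304/304 at n = 608): positives draw narrowing from
[0.3, 0.7], negatives have uniform width, and width (5–9 px), curvature
(2–10 px deflection) and noise vary per patch, scaled with the frame for
non-default sizes. The generator produces a single non-bifurcating vessel
with additive Gaussian noise; real angiograms have vessel trees,
structured background (ribs, catheter, diaphragm), Poisson-ish noise and
contrast variation. Passing tests on this generator therefore demonstrate
that the pipeline is *internally* coherent — filters enhance what was
planted, the selector finds features that genuinely discriminate the
planted lesion — not that the reported real-data accuracy transfers.

All generators are pure functions of their seed; every run draws from a
single master seed via labelled stream derivation (`derive_seed()`).

## Problem sizes used by the test-suite experiments

The validation experiments run at desk scale, chosen once: oracle
comparisons use 12-feature problems (4095-subset exhaustive search is
exact there), planted-recovery and diversity-trend batteries use 30
features with 5 informative at effect size 2, populations of 20 for 60 to
100 generations with 15- to 25-iteration refinement schedules, and
10-seed batteries with paired seeds for with/without-diversity
contrasts. The recovery battery uses 300 samples with a 60-sample
validation split: the holdout accuracy is quantized at 1/|validation|,
and the marginal accuracy gain of the 4th and 5th planted features
(about 2 percentage points at effect size 2) must exceed that quantum
for those features to be part of the fitness optimum at all — with
coarser validation splits the optimum genuinely excludes them, which is
a property of the objective, not of the search. The reference
experiment scale (473 features, population 100, 1000 generations, 30
trials) is available through `run_config()` defaults but is not
exercised by the tests.

## Known limitations

* The SVM backend is libsvm with fixed cost C = 1; the reference method's
  solver and regularization are unstated, so real-data accuracies are
  contract-checked on synthetic data only, never asserted against the
  published database numbers.
* The Salem filter and the GA baseline are documented stand-ins (see
  above).
* The 228-feature catalog matches the reference catalog's families and
  naming scheme, not its exact 473 columns.
* Skeleton branch lengths are pixel counts, not geodesic lengths; for
  64×64 patches the difference is immaterial for class separation but
  matters if absolute lengths are interpreted.
* `glcm_haralick()`'s sum/difference statistics use the corrected
  convention (sum variance about the sum average); natural logarithms
  throughout.
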