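---
title: "Methods: possibilistic semi-supervised classification with multi-source model adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: possibilistic semi-supervised classification with multi-source model adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mapca)
```

## The problem

EEG-based emotion recognition (and many related biosignal tasks) violates
the two assumptions most semi-supervised learners rest on. First, labels are
expensive: a target recording session typically yields a large feature
sample of which only a sliver is annotated. Second, data are not identically
distributed across subjects, sessions, or devices, so a classifier trained
on one domain degrades on another, and classifiers pre-trained on public
datasets cannot simply be reused. `mapca` addresses both at once: it fits a
transductive kernel classifier on the partially labelled target sample while
adaptively weighting a set of pre-trained *source models*, so that only
sources whose decision behaviour matches the target contribute.

A third, practical concern drives the model's clustering machinery: real
EEG feature sets contain noise and outliers. Conventional clustering
assumptions give every instance a full unit of membership mass to
distribute, which forces outliers to commit to classes and lets them drag
the decision boundary. Here memberships are *possibilistic* — each instance
holds an independent membership $v_m \in (0,1]$ per class — so an outlier
can be "a little bit of nothing".

## Model

Let $X = \{x_1,\dots,x_n\} \subset \mathbb{R}^d$ with one-hot labels $y_i
\in \mathbb{R}^M$ for $i \le l$, $l \ll n$. Three ingredients:

**Local consistency via local weighted means.** A kNN graph (Euclidean
distances, $k$ neighbours, self excluded, ties to the lowest index) carries
Gaussian weights $D_{ij} = \exp(-\tau\|x_i-x_j\|^2)$. Each instance's local
weighted mean $\hat x_i = \sum_{j \in Ks(x_i)} D_{ij}x_j / \sum_j D_{ij}$
is a convex combination of its neighbours; the loss penalises disagreement
between an instance's prediction and its LWM's prediction, a smoothness
prior on the data manifold. The LWM sum runs over the *directed* neighbour
set $Ks(x_i)$; the graph object additionally stores the symmetrised weight
matrix (max of the two directed assignments) for inspection and export.

**Possibilistic memberships with fuzzy-entropy regularisation.** Unlabelled
instances enter the loss through $v_m^2(x_j)\,\|f(x_j)-c_m\|^2$ terms
against the class prototypes $c_m$, plus the fuzzy-entropy term
$C\sum_{m,j}(v^2\ln v^2 - v^2)$. The entropy term yields the closed-form
update $v_m(x_j) = \exp(-(\|f(x_j)-c_m\|^2 + \lambda_s\|f(\hat
x_j)-c_m\|^2)/(2C))$ and caps the influence any single instance can exert:
an instance far from every prototype receives uniformly small $v$ and
nearly drops out of the fit.

**Divergence-constrained model adaptation.** Source classifiers
$\{W_i^s\}_{i=1}^q$ are carried as dual coefficients over the target
sample. The adaptation term $\beta(\sum_i \gamma_i A_i + \eta\|\gamma\|^2)$
pulls the target model toward sources in proportion to their simplex
weights $\gamma$, where $A_i$ is the target-scatter-weighted model
discrepancy, estimated empirically as $A_i = \frac1n\|K(\alpha -
\alpha_i^s)\|_F^2$ — the mean squared disagreement of decision values on
the target sample. Smaller $A_i$ (more relevant source) earns larger
$\gamma_i$.

By the representer theorem the decision model is $f(x) = \alpha^\top k(x)$
with $\alpha \in \mathbb{R}^{n\times M}$, and all losses reduce to
expressions in the Gram matrix $K$ and the cross-Gram $\bar K$ between LWM
points and samples.

## Optimisation

Alternating minimisation with three exact coordinate updates:

1. $\alpha$: the objective is a convex quadratic given $(V,\gamma)$; we
   solve the normal equations $H\alpha = B$ obtained by differentiating the
   objective with $W = K\alpha$ directly, where
   $H = KS_LK + \lambda_s\bar K^\top S_L\bar K + K\hat VK +
   \lambda_s\bar K^\top\hat V\bar K + \lambda K +
   \frac{\beta}{n}(\sum_i\gamma_i)KK$ and
   $B = (K+\lambda_s\bar K^\top)S_L\tilde Y + (K+\lambda_s\bar K^\top)V_{sq}
   + \frac{\beta}{n}KK\sum_i\gamma_i\alpha_i^s$.
   ($S_L$: labelled indicator diagonal; $\hat V$: summed squared
   memberships; $V_{sq}$: squared memberships against one-hot prototypes.)
   The tests verify $\partial Q/\partial\alpha = 0$ against an
   independently assembled system and against a generic numerical
   minimiser.
2. $V$: the exponential closed form above, entrywise; it is the global
   minimiser of each one-dimensional subproblem on $(0,1]$ (verified
   against a grid-search oracle).
3. $\gamma$: pairwise coordinate descent on the simplex QP
   $\min_\gamma \gamma^\top A + \eta\|\gamma\|^2$, sweeping all index pairs;
   for a pair with mass $s$, the unconstrained optimum $s/2 +
   (A_j-A_i)/(4\eta)$ is clamped to $[0,s]$. The exact solution is also the
   Euclidean projection of $-A/(2\eta)$ onto the simplex, which the test
   suite uses as an independent oracle. As $\eta \to \infty$ the weights
   tend to $1/q$; with well-separated scores and small $\eta$ the solution
   is sparse.

Each update globally minimises its subproblem, so the objective chain is
non-increasing across partial updates and cycles; the suite asserts this at
relative tolerance $10^{-9}$. Stopping uses a window rule: with window
$\hbar$ and threshold $\varepsilon$, iteration halts when
$|\max\Theta - \min\Theta| / |\max\Theta| < \varepsilon$ over the last
$\hbar$ objective values, or after $N$ cycles.

## Parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| $k$ | neighbours per instance | 5 | ties at the k-th distance keep the lowest index |
| $\tau$ | graph Gaussian width | $1/(2\,\mathrm{med}\|x_i-x_j\|^2)$ | median heuristic, scale-robust |
| $\sigma$ | kernel width | $1/d$ | shared across families; per-family override |
| $\lambda$ | RKHS penalty | 1 | must be $>0$ |
| $\lambda_s$ | LWM-consistency weight | 1 | 0 disables the LWM terms |
| $C$ | fuzzy-entropy weight | 1 | $C\to\infty$: all $v\to1$; $C\to0^+$: $v\to0$ |
| $\beta$ | adaptation weight | 1 | 0 = single-domain fit (`sspca()`) |
| $\eta$ | $\gamma$ ridge | 1 | large = uniform weights, small = concentration |
| $N,\hbar,\varepsilon$ | stopping | 50, 5, $10^{-4}$ | window rule above |

The balance weights are tuned empirically over the log grid
$10^{-4},\dots,10^4$ (`default_grid()`, `grid_search()`); cross-validation
is deliberately not offered for the adaptation setting because a held-out
source split is not representative of a shifted target.

**Membership LWM weighting.** The stationarity condition of the membership
subproblem carries $\lambda_s$ on the LWM distance, while the plain
exponential form drops it; both are implemented
(`membership_lwm_weighted`, default `TRUE`), the default being the
derivative-consistent choice — with it, the membership update is exactly
the minimiser of the package's own objective for any $\lambda_s$, which is
what the monotone-descent guarantee requires.

**Class prototypes.** $c_m$ is the one-hot basis vector $e_m$, placing
labelled targets and cluster prototypes in the same $M$-dimensional output
space.

**Source representation.** A source model trained elsewhere is re-expressed
over the target sample by kernel least-squares projection of its decision
values (`train_source()`); the adaptation term multiplies source models by
target Gram matrices, which requires this shared representation. Projection
is exact (hence idempotent) whenever the target Gram is nonsingular.

## Numerical choices

* $v^2\ln v^2$ is evaluated as 0 at $v=0$ (its continuous limit);
  memberships are clamped below at $10^{-300}$ against underflow.
* $H\alpha=B$ is solved directly; only if the solve fails is a ridge jitter
  of $10^{-10}\,\mathrm{tr}(H)/n$ added (kernel Gram products are often
  near-singular), and a second failure raises an error advising a larger
  $\lambda$.
* The $\gamma$ sweep stops when no coordinate moves by more than
  $10^{-12}$, which puts the result within $\sim10^{-8}$ of the exact QP
  solution.
* Membership initialisation defaults to all-zero (the first model is fitted
  from labelled data alone); all-one and seeded-random initialisations are
  available.
* Prediction ties (equidistant prototypes) resolve to the lowest class
  index.
* Multi-kernel learning concatenates feature maps, realised exactly as the
  sum of the member Gram matrices — all solver shapes are unchanged, and
  additivity is asserted to $10^{-12}$.

## The synthetic generator

`make_domain()` emulates the structure of cross-subject/cross-session EEG
feature data without simulating EEG itself: Gaussian class blobs
(differential-entropy features are continuous, moderate-dimensional, and
roughly Gaussian per class), a rigid per-domain transform — translation
plus a rotation in the first-two-feature plane — standing in for covariate
and conditional shift between domains, box-uniform outliers with arbitrary
labels, and an exactly stratified labelled subset. Defaults: 3 classes in 5
dimensions, 30 instances per class, unit class standard deviation, class
means at $3e_m$ (a 3-sigma separation), 10% labelled. Everything is
deterministic given the config, which carries its seed.

What it does **not** emulate: temporal structure, channel correlation,
heavy-tailed artefacts, label noise on genuine inliers, and class
imbalance. Passing tests therefore demonstrate the optimisation and
adaptation machinery under controlled shift, not performance on real EEG
recordings.

## Design of the experiments

The package's benchmark (`make_recovery_task()`) pairs the target with one
source drawn from the target's own law and one *irrelevant* source whose
class means are cyclically permuted and translated by 0.5 per coordinate.
The permutation matters: a merely far-translated source projects to
near-zero dual coefficients on the target (its kernel responses vanish), so
fusing it would only shrink the model; the permuted source is confidently
*wrong* on the target, so the uniform-weight ablation measurably loses
accuracy and the benefit of optimal weighting is visible.

The experiments run with $\beta = 100$ and $\eta = 0.1$ (values from the
standard tuning grid). Two a-priori considerations fix these: $\gamma$ lives
on the simplex, making the adaptation term $O(1)$ while the data losses are
$O(n)$, so $\beta/n \approx 1$ (here $n = 90$) puts the two on an equal
per-instance footing; and source *selection* requires a small $\eta$, since
large $\eta$ forces uniform weights by construction. Experiment sizes — 20
replicate seeds for the recovery and outlier experiments, 10 for the
multi-kernel comparison, instances of 10–20 samples for the
coordinate-update property checks — keep each experiment's full run in the
order of seconds while leaving the medians stable across seeds.

```{r example}
task <- make_recovery_task(seed = 1)
fit <- mapca(task$target$X, partial_labels(task$target),
             sources = task$sources,
             control = mapca_control(beta = 100, eta = 0.1))
fit
transductive_accuracy(fit, task$target$y)
```

## Known limitations

* Dense $n \times n$ graph and Gram algebra: intended for desk-scale
  targets (thousands of instances at most), not streaming or GPU use.
* The objective is non-convex jointly; alternating minimisation reaches a
  local optimum whose quality depends on the membership initialisation.
* Sources must be expressible over the target sample; a source whose
  kernel responses on the target are uniformly near zero carries no usable
  information (its projection is $\approx 0$), and adaptation can only
  shrink toward it.
* The $\gamma$ ridge $\eta$ trades off selection sharpness against
  robustness to misleading adaptation scores; there is no automatic rule.
* Transductive accuracy is the primary metric; inductive generalisation is
  available through `predict()` but is not what the objective optimises.
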