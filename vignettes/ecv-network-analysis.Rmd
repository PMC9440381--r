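---
title: "Edge contribution values for differential gene-network analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge contribution values for differential gene-network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecvnet)
```

## Motivation and model

Whole-blood RNA-Seq cohorts for rare diseases are small: the shape this
package is built around is roughly twenty samples in two unbalanced groups
(eleven cases, nine controls). At that size, marginal differential
expression is underpowered, and group differences that live in
*relationships between genes* — a regulator whose influence on its target
is lost in patients — can be invisible in a volcano plot. The workflow
here therefore contrasts groups at the level of network edges.

One directed acyclic network (the *basal network*) is estimated from all
samples pooled. Each gene $v$ is modelled as an additive smooth function
of its parents on the standardized $\log_2(\mathrm{TPM}+1)$ scale,

$$x_v = \mu_v + \sum_{u \in \mathrm{pa}(v)} f_{uv}(x_u) + \varepsilon_v,
\qquad \varepsilon_v \sim \mathcal{N}(0, \sigma_v^2),$$

with every $f_{uv}$ a centered cubic B-spline smoother. Structures are
scored by a BIC-penalized Gaussian likelihood,
$-2\,\ell + \log(n)\,k$, where $k$ counts the intercept, the spline
coefficients (`spline_df` per edge) and the residual variance per node.
The score is decomposable, so the network score is exactly the sum of its
node scores; tests assert this to $10^{-6}$.

The **edge contribution value** of edge $u \to v$ in sample $s$ is the
fitted, centered parent effect evaluated at that sample's parent
expression:

$$\mathrm{ECv}(u \to v, s) = f_{uv}\!\left(x_u^{(s)}\right).$$

Edges are ranked by the absolute difference in group-averaged ECv,
$\Delta = |\overline{\mathrm{ECv}}_{\text{case}} -
\overline{\mathrm{ECv}}_{\text{control}}|$, and the top fraction $q$
(default $10^{-5}$, the "top 0.001%" rule) is selected. Weakly connected
components of the selection are the subnetworks; each contributes its
best-AUC member as a representative marker, which then passes through a
classification tree, stepwise-AIC logistic regression, an interaction
screen and leave-one-out cross-validation.

## What ECv can and cannot detect

Because $\mathrm{ECv}(u \to v, s)$ depends on the sample only through the
parent $u$, the group contrast of an edge is driven entirely by
between-group differences in the *parent's* expression distribution,
propagated through the fitted smoother. Two consequences matter for
interpreting results:

* An edge whose parent shifts between groups — for instance because the
  parent is downstream of a genuinely altered regulatory input — shows a
  large $\Delta$. This is the detection channel the method exploits.
* A *purely conditional* change, where the dependence of the child on the
  parent is altered (even ablated) while the parent's marginal
  distribution is untouched, is invisible on that edge itself: the basal
  smoother is a single pooled fit, so case and control mean ECv agree in
  expectation. Such a change surfaces instead on edges *out of* the
  affected child, whose input distribution it shifts.

The synthetic experiments in the test suite quantify both sides. In the
ablation experiment (five edge functions multiplied by zero in the case
group, thirty genes, thirty samples per group) the recall of the ablated
edges themselves among the top-five $\Delta$ECv ranks is near chance
(~0.05 across ten simulations) — exactly as the parent-evaluated
definition predicts — while edges downstream of the ablated children
carry the signal. We report this honestly rather than redefining either
the score or the recall metric; an edge-level contrast that also captures
conditional change would need a two-group ECv formulation, which is out
of scope here.

## Structure search

The search is greedy hill-climbing over add, delete and reverse moves,
restricted to each gene's `candidate_parents_k = 10` strongest partners
by absolute Spearman correlation, with at most `max_parents = 3` parents
per gene and acyclicity enforced by an incremental reachability check.
Moves are scanned in a deterministic lexical order and the first
improving move is taken; restarts rescan in seeded random orders. On top
of the restarts we run seeded *iterated local search*: the incumbent is
perturbed by deleting each edge independently with probability 0.35 and
re-climbed, keeping improvements. Plain first-improvement restarts alone
proved order-sensitive — competing near-optimal orientations of edge
clusters made independent runs disagree — whereas with the ILS phase the
search reliably reaches the same optimum from different seeds whenever
the data identify one, which is what makes the triplicate-stability check
(below) meaningful.

Local scores are cached across all climbs (they depend only on the child
and its parent set), and the per-gene spline bases are precomputed once,
which keeps a 30-gene fit at $n = 200$ around a few seconds.

Constant genes are dropped with a warning before the search. Ill-
conditioned design blocks fall back to a lightly ridge-penalized solve.

## Reproducibility of the estimate

Mirroring the practice of running the estimator several times and
confirming the structure is unchanged, `check_reproducibility()` fits the
network under three seeds and reports whether the edge sets are identical
together with their pairwise Jaccard indices. On strong-signal synthetic
data (ten genes, moderate density, two hundred pooled samples) the three
runs agree exactly; on weak data the function degrades gracefully to a
Jaccard report rather than failing. Everything downstream of a fixed
`(input, configuration, seed)` triple is deterministic — the pipeline
writes byte-identical artifact directories on rerun, including the seeded
LOOCV ensemble.

## The synthetic-data generator

`generate_truth()` and `simulate_counts()` emulate the study conditions:
two unbalanced groups (defaults 11 vs 9), tens to hundreds of genes, TPM-
scale expression, and group differences injected **only** through edge
functions — never through marginal intercepts — so that edge-level
analysis, not marginal DE, is the appropriate detector.

Design choices, fixed once:

* **Edge functions** are monotone cubic B-splines on a fixed knot grid
  (sorted uniform coefficients, random direction), continuing linearly
  beyond the grid. Monotone responses mirror activation/repression and
  keep rank-correlation screening informative. Each function carries a
  nonzero activity offset, so ablating an edge removes both a dependence
  and a mean input to its child, as losing a regulator does.
* **Inputs are standardized.** Each function takes the parent's
  standardized latent deviation; node deviation scales are propagated
  analytically at generation time. This bounds latent variance along the
  graph regardless of depth.
* **Latent scale.** `amplitude = 0.8` (response spread, log2 units) and
  `noise_sd = 0.35` give per-gene biological variability below ~1.2 log2
  units — typical of bulk RNA-Seq — with a per-edge signal-to-noise
  ratio around five.
* **Counts.** Latent log2 expression maps to expected abundance, then to
  Poisson counts with per-sample library sizes and per-gene length
  weighting (negative binomial behind an overdispersion switch). The
  matrix also contains five-fold independent *background genes*: without
  them, TPM over a tiny gene universe acquires a compositional common
  mode (the log library total fluctuates with every gene) strong enough
  to swamp the network signal — a real transcriptome buffers the
  denominator, and the background genes emulate that. The network itself
  is then estimated on the network genes, as one would estimate it on a
  preselected panel of a full transcriptome.

What the generator does **not** emulate: batch effects, cell-type
composition shifts, gene-length biases beyond the TPM model, and
read-level error. Passing tests therefore demonstrate correctness of the
pipeline's logic and its behavior under idealized sampling noise, not
robustness to those artifacts.

Simulation sizes used by the test suite — 30-gene/~40-edge networks with
200 pooled samples for recovery (mean skeleton F1 about 0.78, asserted at
0.6), ten-gene networks for stability, 100 seeds for the Monte-Carlo
oracles at 50 samples per group — were chosen as the smallest problems
that exercise each property with comfortable statistical margin.

## Decisions on underspecified details

Several details of this kind of workflow are conventionally left open; the
package fixes them as follows and keeps alternatives behind switches:

* The estimator consumes **standardized log2(TPM+1)**; raw-TPM fitting is
  numerically fragile with spline regressors and is retained only behind
  `standardize = FALSE`.
* The read-count filter before the volcano comparison keeps genes with
  **total count across samples strictly greater than** the threshold
  (default 6).
* ECv contributions are kept **signed** per sample and the absolute value
  is applied to the difference of group means; mean-of-|ECv| is available
  via `ecv_absolute = TRUE`.
* Subnetwork correlations are Pearson correlations **on TPM**; AUCs are
  computed on TPM (AUC is invariant to monotone transforms, so this
  choice only matters for reporting cutoffs, which follow the TPM axis).
* LOOCV uses the **single primary marker** by default (the stepwise
  winner, falling back to the best-AUC representative); a flag evaluates
  all representatives.
* The selection floor (`min_selected_edges = 1`) exists because
  `round(q * E)` is zero on desk-scale networks; the default fraction
  only bites at millions of edge instances.

## Numerical choices

Spline bases drop their first column (absorbed by the node intercept) and
evaluate with linear extrapolation beyond the boundary knots, so ECv is
defined for out-of-range samples. Residual variances are clamped at
$10^{-12}$ to keep degenerate (interpolating) fits finite. Logistic fits
detect separation via boundary fitted probabilities and refit with a
$10^{-6}$ ridge on standardized covariates (Newton with step halving);
the reported AIC uses the unpenalized likelihood at the penalized
coefficients — separation is routine in leave-one-out folds of twenty
samples. Ties are broken deterministically everywhere: lexical by
(parent, child) for edges, lower gene index then smaller threshold for
tree splits, smallest cutoff for Youden ties.

## Known limitations

* The stepwise-AIC search equals the exhaustive best subset when one
  marker dominates, but can miss small joint AIC gains of noise-gene
  pairs in diffuse-signal regimes; the tests cover both regimes.
* Representative selection and discrimination run on the same samples,
  so null-data discrimination estimates are optimistically biased — an
  inherent limitation of same-data variable selection and evaluation at
  this cohort size. The null-pipeline test documents the measured
  behavior.
* Orientation of individual edges in near-linear relationships is only
  weakly identifiable at these sample sizes; recovery is therefore judged
  at skeleton level.
* With twenty samples the basal network overfits (more edges than the
  truth); the downstream ECv contrast, not the structure itself, is the
  robust readout at study scale.
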