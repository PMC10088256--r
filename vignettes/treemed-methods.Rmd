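---
title: "Phylogeny-guided mediation testing: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogeny-guided mediation testing: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treemed)
```

## The model

A microbiome mediation analysis asks whether a treatment `T` changes the
outcome `Y` *through* the microbial composition. `treemed` avoids a single
joint model over hundreds of relative abundances by working on a rooted
binary tree over the taxa: each internal node `j` defines a
*subcomposition* — the pair of abundances aggregated to its left and right
child — and the local mediator is the log-ratio

$$M_{ij} = \log\frac{\text{left}_{ij} + c}{\text{right}_{ij} + c},$$

with pseudocount $c$ (default 0.5). Subjects whose two aggregated counts are
both zero carry no information about that subcomposition and are removed
from that node's model only. Ratios make the unknown total microbial load
cancel, so the models respect compositionality, and the node-level
mediators are modeled as independent across nodes (a Polya-tree-style
decomposition), which is what later licenses treating the node p-values as
asymptotically independent.

Each node carries two regressions: a distribution-free linear model of
$M_{ij}$ on confounders and treatment (coefficient $\alpha_j$), and a GLM of
$Y$ on confounders, treatment, and $M_{ij}$ (coefficient $\beta_j$;
identity link for continuous outcomes, logit for binary). No distributional
assumption is placed on the subcomposition itself, which keeps the first
model robust to overdispersion and outliers.

## Testing the composite null

The no-mediation null at a node, $\alpha_j\beta_j = 0$, is the union of
three disjoint hypotheses: both coefficients zero ($H_{00}$), only the
treatment association present ($H_{10}$), only the outcome association
present ($H_{01}$). The classical joint significance test treats
$p_{\max} = \max(p_\alpha, p_\beta)$ as Uniform(0,1) under the null, which
is only correct under the least favourable configuration; across a tree
where most nodes are deep in $H_{00}$ it is severely conservative (its null
CDF there is $p_{\max}^2$, not $p_{\max}$). Sobel's normal-theory test has
the same defect. `treemed` instead computes the exact mixture CDF

$$p_j = \pi_{00}\,p_{\max}^2
      + \pi_{10}\,p_{\max}\Pr(P_\alpha \le p_{\max}\mid \alpha\ne 0)
      + \pi_{01}\,p_{\max}\Pr(P_\beta \le p_{\max}\mid \beta\ne 0),$$

which requires the three proportions and the two alternative "power
functions". The large number of parallel node models is exactly what makes
these estimable.

**Association p-values.** Both nulls are tested with classical Rao score
statistics from the null-restricted fits (for $\alpha$: residuals of the
mediator on confounders scored against the confounder-residualised
treatment; for $\beta$: the GLM efficient score of the mediator from the
`(X, T)`-only fit), referred to $\chi^2_1$. These are standard
constructions chosen because only "score statistics" are specified for the
procedure; on continuous outcomes they agree with the Wald/F tests to
within 0.01 at n = 200 (verified in the test suite). A permutation variant
is provided for small samples: Freedman-Lane residual permutation (for
$p_\alpha$, permute residuals of `T ~ X`; for $p_\beta$, residuals of
`M ~ (X, T)`), recomputing the score statistic each time, with adaptive
early stopping (stop at 100 exceedances or 10,000 permutations;
$p = (b+1)/(B+1)$). Freedman-Lane is our choice rather than a stated
requirement: it preserves the confounder structure, which raw-variable
permutation would break. One master seed drives per-node deterministic
streams, so permutation results do not depend on node processing order.

**Null proportions.** The fraction of nodes with $\alpha = 0$
($\pi_{0\bullet}$) is estimated by the empirical characteristic function
method: p-values are converted to signed z-scores
$Z = \mathrm{sign}(\hat\alpha)\,\Phi^{-1}(1-p/2)$ and

$$\hat\pi_{0\bullet} = \inf_{0 \le t \le \sqrt{\log J}}
  \int_{-1}^{1} (1-|\xi|)\,\mathrm{Re}\,\varphi_J(t\xi)\,e^{t^2\xi^2/2}\,d\xi ,$$

evaluated by a trapezoid rule on a 201-point $\xi$-grid and the infimum
over a 101-point $t$-grid (the functional is prescribed; the discretisation
is ours, and the implementation is checked against an independent
quadrature to 1e-6). Estimates are clamped to $[1/J, 1]$, and with fewer
than 20 usable nodes the estimator falls back to 1 with a warning (the
sample is too small for the Fourier machinery; 1 is the conservative
choice). $\hat\pi_{\bullet 0}$ is obtained the same way from the
$p_\beta$'s. Two combinations into $(\pi_{00}, \pi_{10}, \pi_{01})$ are
offered: the default "product" rule
$\hat\pi_0 = \hat\pi_{0\bullet}+\hat\pi_{\bullet 0}-\hat\pi_{0\bullet}\hat\pi_{\bullet 0}$,
and a "maxp" rule that estimates $\pi_0$ directly from the $p_{\max}$'s
(using the unsigned conversion $Z=\Phi^{-1}(1-p)$, since $p_{\max}$ has no
natural sign). Negative components, possible under "maxp" in finite
samples, are clamped to zero and the triple renormalised to sum to one. On
null data the two approaches agree to within 0.15 per component (asserted
in the tests).

**Power functions.** The marginal density of, say, the $p_\alpha$'s is the
mixture $\pi_{10} f(p\mid\alpha\ne 0) + (\pi_{00}+\pi_{01})$. The marginal
is estimated by the Grenander estimator — the left derivative of the least
concave majorant of the empirical CDF, the NPMLE of a decreasing density —
and the conditional density recovered as
$\max\{(\hat f - \hat\pi_{\mathrm{null}})/\hat\pi_{\mathrm{alt}},\,0\}$,
integrated to a CDF and renormalised to 1 at $p = 1$. Evaluation between
knots is by linear interpolation of the integrated piecewise-constant
density. When the alternative mass is zero the power function is the
constant 1, which reduces the mixture p-value to its asymptotic form.

## Node selection and the global test

The mixture p-values are asymptotically independent and (under exact
mixture weights) uniform at null nodes, so mediating nodes are selected by
the standard BH step-up procedure. The community-level test combines all
node p-values with the weighted harmonic mean
$\mathring p = (\sum_j w_j)/(\sum_j w_j/p_j)$, equal weights $1/J$ by
default. (The harmonic-mean form is used deliberately: the reciprocal of a
weighted arithmetic mean of p-values is not a p-value and can exceed 1;
the harmonic mean is the construction with the known heavy-tailed null.)
Its null distribution: $1/\mathring p - \log J - (1-\gamma)$ follows the
standard Landau law, the maximally skewed stable law of index 1 with scale
$\pi/2$ — equivalently a stable law with location $\log J + 0.8744$ in the
common convention. The tail probability is computed by direct quadrature of
the Landau tail integral for moderate arguments, Gil-Pelaez inversion of
the characteristic function near the centre, and a three-term asymptotic
series in the far tail; the three regimes agree to a relative 1e-4 at the
seams and match an independent stable-law implementation to 1e-7 (frozen
reference values in the tests). A single p-value is returned unchanged —
the combination is exact there. Fisher's combination is available behind
`combiner = "fisher"` for dense-signal settings, where the harmonic mean's
sparse-signal optimisation costs power.

Degenerate nodes — fewer than `max(10, ncol(X) + 3)` informative subjects,
a constant mediator or treatment among them, or a non-positive score
variance — are excluded from the proportion estimation, the selection, and
the combination, whose equal weights are renormalised over the remaining
nodes. The threshold is our choice (the regression is unidentifiable below
it); it only binds at nodes dominated by very rare taxa.

## The synthetic-data generator

The generator emulates the accompanying simulation design. A random rooted
binary tree over `L = 100` taxa and a log-normal baseline abundance profile
(sd of log abundance 2, sorted so OTU1 is the most abundant) stand in for
the real 900-subject cohort the original study resampled; per-subject
compositions are Dirichlet perturbations of the profile (concentration 50,
a realistic between-subject overdispersion for stool communities) and
counts are multinomial at depths uniform on [10,000, 50,000]. Treatment
effects are planted by adding `Binomial(N_i, A f_k)` counts to taxon `k`
for every subject in one randomly chosen arm (`A = 0.5`; `f_k` the taxon's
average observed proportion). Outcomes follow zero-sum log-contrast models:
`Y = beta_T T + sum_k beta_k log f_ik + e` with `beta_T ~ U(0,1)`,
`beta_k ~ U(0, B = 0.5)` centred to sum to zero, and standard normal
errors (`sigma = 1`; the residual scale is unstated in the design, so it is
fixed and documented here); binary outcomes use the logistic analogue.
Proportions entering the outcome model are computed after adding the
pseudocount so the logs are finite. Null scenarios keep the treatment- and
outcome-associated taxon sets disjoint; alternatives make them equal,
either as random 3-leaf clades ("clustered", one clade per 3 mediators) or
scattered draws.

What the generator does *not* emulate: the taxonomic correlation structure
of a real phylogeny (the tree is random), real zero-inflation patterns, and
real depth distributions. Passing calibration tests on this generator
therefore demonstrates the statistical machinery is correct under the
stated sampling model, not that any particular real cohort will show the
same operating characteristics.

## Operating characteristics, and an honest account of two gaps

At the study scale used in the tests (n = 200, 100 taxa, 500 replicates per
null setting, both outcome types), the global test's empirical type I error
stays at or below 0.05 plus three binomial standard errors in all five null
mixtures, BH node selection controls the empirical FDR at 0.05, and the
mixture-based node test finds the planted clade's most recent common
ancestor more often than joint-significance and Sobel tests run on the
identical fits. Two caveats, both reproducible with `run_replicates()`:

* Under the pure null the global p-values are mildly superuniform (mean
  around 0.56 rather than 0.50). The proportion estimator's infimum is
  downward-biased by a few percent at J = 99, which moves weight from the
  quadratic to the linear mixture terms, and with a concave alternative CDF
  the mixture p-value can never drop below $\pi_{00}p_{\max}^2$-plus; the
  result is a uniform few-percent deficit of small node p-values that the
  harmonic mean amplifies. Feeding $p_{\max}^2$ into the same combination
  is exactly calibrated, which isolates the effect to the plug-in mixture.
  This is the same conservatism visible in the method's published
  calibration tables.
* Under null mixtures with many treatment-associated nodes the effect can
  flip: the proportion estimator under-detects weak (diluted) alternatives,
  and since the estimated power functions are capped at 1 they cannot fully
  compensate, leaving the global rate around 0.06-0.07 at the strongest
  mixture we simulate — still within three standard errors of nominal, but
  above the published real-data-based figures, whose sparser baseline
  produces weaker ancestor dilution.

## Numerical choices

P-values are clamped to `[1e-15, 1 - 1e-15]` before z-conversion; zero
p-values entering the harmonic mean are clamped to `1e-15` with a warning;
mixture p-values are floored at `1e-300`. Ties in the Grenander input are
collapsed before the hull construction; an all-identical p-value vector
yields a degenerate step CDF with a warning. Multifurcations are resolved
deterministically into a left-leaning cascade following input child order
(the method is defined only on binary trees and no resolution rule is
canonical, so we pick one and keep it stable); internal nodes are indexed
in post-order, and node identifiers are reported with the leaf labels of
their children's subtrees since no cross-package node numbering can be
assumed. Branch lengths are ignored throughout — only the topology enters
the method. Leaf/count-table mismatches are an error unless `prune = TRUE`
is passed, so data errors are not silently hidden, and the outcome type is
never guessed from the data (0/1-coded continuous scores would be
misclassified silently).

## Problem sizes in the shipped tests

The packaged test suite runs the five null mixtures at 500 replicates for
each outcome type and a 300-replicate clustered-alternative study — sizes
chosen so the Monte-Carlo standard error of a rate near 0.05 is about 0.01,
tight enough to detect miscalibration twice that size. The acceptance
script repeats the five continuous-outcome null settings at 500 replicates
from a user-supplied seed. Larger replicate counts only narrow the
binomial error bars; the summaries include those standard errors so users
can scale the runs to their own precision needs.

## Known limitations

Tree misspecification dilutes clustered signal (scattered-mediator
scenarios remain testable via `clustered = FALSE`); the treatment must be
binary; treatment-mediator interactions and exact conditional logistic
tests are out of scope; and the node-level mediation "effect" is a test,
not an effect-size estimate — interpreting a selected ancestor node at the
leaf level additionally assumes the two association elements are not
contributed by disjoint descendant sets, which the `pair_screen()`
heuristic can probe but not prove.
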