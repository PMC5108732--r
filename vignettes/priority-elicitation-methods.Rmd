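---
title: "Measuring priorities with AHP, best-worst scaling and ranking cards"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring priorities with AHP, best-worst scaling and ranking cards}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prefrank)
```

## The measurement problem

When a patient cohort must prioritize many criteria — here, thirteen
categories of information that a web portal for people with rare diseases
could offer — no single elicitation method is canonical. `prefrank`
implements three established instruments on a common criteria hierarchy and
the machinery needed to compare them:

* the **Analytic Hierarchy Process (AHP)**: ratio-scaled pairwise
  judgments, eigenvector priority weights, consistency screening, and group
  aggregation;
* **best-worst scaling, object case (BWS Case 1)**: best and worst picks
  from small choice sets, scored by count analysis;
* **ranking cards**: a plain ordinal sort, ties allowed.

The package's focus is methodological: how much do the resulting priority
*rankings* depend on analytic choices that the AHP literature leaves open —
the consistency threshold, the aggregation scheme, sampling noise — and how
well do the three instruments agree?

## The hierarchy and the AHP model

A `criteria_hierarchy` is a tree with the study goal at the root. The
children of each *queried* node form a comparison block; the shipped
fixture (`info_hierarchy()`) has a four-criterion block at level two and
three three-criterion blocks at level three, hence
$\binom{4}{2} + 3\binom{3}{2} = 15$ pairwise comparisons per respondent.
Level-four subcategories exist in the tree but are not elicited: with them
the questionnaire could not have 15 comparisons.

For each block a respondent supplies the upper triangle of a positive
reciprocal matrix $A$ on the Saaty grid $\{1/9, \dots, 1, \dots, 9\}$,
$a_{ij}$ being how many times criterion $i$ outweighs criterion $j$. The
priority vector $w$ is the Perron eigenvector, $A w = \lambda_{\max} w$,
normalized to $\sum_i w_i = 1$; we compute it by power iteration with L1
normalization (tolerance $10^{-12}$ on successive iterates, at most
10\,000 iterations, non-convergence is an error). $\lambda_{\max}$ comes
from the L1 Rayleigh ratio at convergence. Consistency is measured by

$$\mathrm{CI} = \frac{\lambda_{\max} - n}{n - 1}, \qquad
  \mathrm{CR} = \mathrm{CI} / \mathrm{RI}(n),$$

with the usual random-index table $\mathrm{RI} = (0, 0, 0.58, 0.90, 1.12,
1.24, 1.32, 1.41, 1.45)$ for $n = 1..9$ (configurable; the table is a
convention, not a law). A $2 \times 2$ reciprocal matrix is always
consistent, so CR is defined as 0 there rather than dividing by
$\mathrm{RI} = 0$. Respondents are screened at $\mathrm{CR} \le 0.1$
(strict) or $\le 0.2$ (lenient); by default only the level-two block is
screened, which is how such studies usually phrase their inclusion rule —
`screen_blocks = "all"` uses the maximum CR across blocks for sensitivity
checks.

Local weights multiply down the tree: the root has global weight 1 and a
block member's global weight is its local weight times the parent's global
weight, so each block conserves its parent's mass. Combined rankings cover
the 13 elicited criteria; a criterion without elicited subcategories is
ranked by its own global weight.

## Group aggregation: AIJ and AIP

Two philosophies exist for turning individual answers into a group answer.
**AIJ** (aggregate individual judgments) merges the matrices first — the
group answers as a new individual — and computes one eigenvector.
**AIP** (aggregate individual priorities) computes each respondent's
weights, screens them, and merges the weight vectors. Each can use the
geometric mean, the arithmetic mean, or the median, giving the six
scenarios that `build_report()` runs.

Only the element-wise geometric mean preserves reciprocity of the merged
matrix exactly (the Aczél–Saaty result), and only geometric AIP
aggregation is guaranteed to respect Pareto dominance. The other centrals
are still implemented because practitioners report them: for AIJ under
arithmetic mean or median we aggregate the *elicited upper triangle* and
mirror reciprocals — aggregating both triangles element-wise would not even
produce a reciprocal matrix — and emit a warning recording the axiom
violation. Geometric and median AIP aggregates no longer sum to one, so
the canonical output is renormalized; the raw magnitudes are kept as an
attribute because the systematic size difference between AIP and AIJ
aggregates is itself a finding one may want to display. Whether the median
variant should be renormalized at all is unstated in the literature we
follow; we report both forms. The median of an even number of values is
the midpoint of the central pair.

For AIP no group judgment matrix exists, so no group CR is defined. We
report the distribution of individual CRs and, clearly labelled as a
diagnostic, the CR of the element-wise aggregated matrix of the included
respondents; we make no claim that this reproduces any particular published
group-CR construction.

Rankings use competition ranks (tied items share the best rank, the next
rank skips), with ties declared below an absolute weight tolerance of
$10^{-9}$ — rank reversals driven by weight differences at that scale are
numerical noise, not findings. `rank_span()` and `rank_reversals()`
summarize how rankings move across scenarios or thresholds.

## BWS count analysis

Each choice set shows three or four criteria; the respondent marks the best
and the worst, two decisions per set, seven sets per respondent in the
study-shaped design (`bws_design()`: a size-$k$ block contributes $k$ sets
of size $k-1$ when $k \ge 4$, a size-3 block its full triple once). Count
analysis tallies per criterion the best count $B_i$, worst count $W_i$ and
appearances $r_i$; the standardized score is $(B_i - W_i)/r_i$ — dividing
by per-criterion appearances keeps the score meaningful under unbalanced
designs, and cancels under balanced ones. Scores are unit-rescaled within
each comparison block, $x \mapsto (x - \min)/(\max - \min)$, so every
block's best criterion is 1.000 and its worst 0.000, which is how such
tables are printed; a pooled mode exists for designs that mix blocks.
All-equal scores within a block have no defined rescaling: that is an
error, with an explicit flat-0.5 fallback under a warning in `bws()`.
Choice-model estimation (conditional logit and friends) is deliberately out
of scope — the count analysis is the target of this package.

## Comparing methods: tie-adjusted concordance

Method agreement is measured by Kendall's $\tau_b$,

$$\tau_b = \frac{C - D}{\sqrt{(n_0 - n_1)(n_0 - n_2)}},$$

with $C$/$D$ the concordant/discordant pair counts, $n_0 = n(n-1)/2$ and
$n_1, n_2$ the tied-pair corrections — ranking data are full of ties, which
$\tau_a$ would ignore. The implementation counts pairs directly and is
tested against exhaustive enumeration. P-values use the tie-corrected
normal approximation to $C - D$ by default; exact permutation enumeration
is available for $n \le 8$. Published studies of this design typically
print $p$ without naming a method, so we do not claim to reproduce any
specific printed p-value.

A group-level $\tau_b$ on a four-item block is too coarse to be
informative (its support is a handful of values), so the default
cross-method statistic is the *pooled within-respondent* $\tau_b$
(`pooled_tau()`, `ahp_bws_tau()`): every respondent contributes the pairs
among their own items, pairs never cross respondents, and counts are summed
before the ratio. Both variants are exposed. Card rankings aggregate
across respondents by median rank with competition re-ranking, keeping
ties; AHP-vs-card correlation is intentionally not computed, since in the
survey design the cards anchor the AHP interview and the comparison would
be circular.

## Rank stability: BCa bootstrap

Small samples make group weights fragile. `ahp_boot()` resamples whole
respondents with replacement — the respondent, not the judgment, is the
exchangeable unit, preserving within-person correlation across blocks —
recomputes the AIP-geometric global weights on each of $B = 1000$
resamples (configurable), and forms bias-corrected accelerated (BCa)
intervals per criterion:
$z_0 = \Phi^{-1}(\#\{\hat\theta^*_b < \hat\theta\}/B)$,
$a = \sum_i (\bar\theta - \theta_{(i)})^3 / \,
6\bigl[\sum_i (\bar\theta - \theta_{(i)})^2\bigr]^{3/2}$ from the
jackknife, endpoints at the $\Phi\!\left(z_0 + \frac{z_0 + z_{\alpha}}
{1 - a(z_0 + z_{\alpha})}\right)$ percentiles (type-7 quantiles). With
$z_0 = a = 0$ this is the plain percentile interval, which is a test case.
Degenerate situations are flagged rather than repaired: an all-equal
resample distribution collapses to a point interval, zero jackknife
variance forces $a = 0$, and an observed value outside its own interval is
reported. $z_0$ and $a$ are computed per criterion independently.

`rank_stability()` turns the intervals into the qualitative statement such
studies make: criteria whose intervals overlap are mutually at risk of rank
reversal (the maximal overlap groups are the cliques of the interval
graph), while an interval overlapping none marks a robust rank.

## The synthetic cohort model

No respondent-level data ship with the package, so every estimator is
validated against a generative model (`synthetic_config()`,
`simulate_study()`) that mirrors the study design while keeping its two
degrees of freedom interpretable:

* **heterogeneity**: respondent block weights are
  $\mathrm{Dirichlet}(\kappa\, w_{\mathrm{true}})$; large $\kappa$ means a
  homogeneous cohort;
* **inconsistency**: judgments invert the ratio model,
  $a_{ij} = \mathrm{snap}\bigl((w_i/w_j)\,e^{\varepsilon}\bigr)$ with
  $\varepsilon \sim N(0, \sigma^2)$, snapped to the nearest Saaty grid
  value in log space so that reciprocity is exact and $1/9 \dots 9$ are
  treated symmetrically;
* **choice noise**: BWS picks maximize/minimize
  $u_i = \log w_i + \mathrm{Gumbel}(0, \text{choice\_scale})$; cards are
  the exact ranking of the respondent's latent global weights.

Defaults are the study shape: 39 respondents, 15 comparisons, 7 BWS sets,
true local weights set to the renormalized published group medians of the
rare-disease information-needs cohort (illustrative, not ground truth),
$\kappa = 50$, $\sigma = 0.15$, unit Gumbel scale. What the model does
*not* emulate: demographics, disease heterogeneity, task-order effects,
incomplete questionnaires, or any dependence between a person's
inconsistency and their preferences. Passing calibration tests therefore
demonstrates that the estimators are correct and stable under this clean
model — not that any particular field sample is well behaved.

One subtlety matters when choosing test profiles. The Saaty grid
quantizes: two criteria whose true weight ratio is within half a grid step
of 1 (e.g. 0.131 vs 0.158) snap to "equal" in every noiseless judgment,
and the published-median profile also contains two sub-criteria whose
*global* weights differ by $4 \times 10^{-5}$. Under that profile the
"true ranking" is not identifiable from the model at any sample size.
Ranking-recovery and noiseless-limit checks therefore use well-separated
profiles (pairwise gaps large relative to sampling noise; for exact
noiseless checks, profiles whose ratios lie on the grid, such as
$8\!:\!4\!:\!2\!:\!1$), while the shipped defaults stay at the published
medians for realism.

## Calibration results computed by the test suite

The test suite (and `scripts/acceptance.R`, which recomputes the same
quantities against the installed package) verifies among other things:

* eigenvector exactness: CR and weight-recovery error below $10^{-10}$ on
  1000 random consistent matrices ($n = 3..9$); power iteration agrees
  with a dense eigensolver to better than $10^{-8}$ on 1000 random
  reciprocal matrices;
* $\tau_b$ equals brute-force pair enumeration on **all** permutation
  pairs up to $n = 5$ and 1000 random tied vectors, exactly;
* AIJ-geometric reciprocity holds to $10^{-12}$; geometric aggregates
  never exceed arithmetic ones; all six scenarios coincide on a
  homogeneous consistent cohort; Pareto dominance is preserved by
  AIP-geometric aggregation;
* the nominal 95% BCa interval for the largest level-two weight attains
  empirical coverage within $[0.90, 0.985]$ over 300 replicates of a
  $n = 30$, $\kappa = 50$, $\sigma = 0.15$ cohort with $B = 1000$ (the
  estimand being the population value of the aggregated statistic,
  approximated once from a 20\,000-respondent cohort);
* mean $\tau_b$ between true and recovered rankings is at least 0.9 at
  $\sigma = 0.1$ ($n = 30$, $\kappa = 50$, 100 replicates), does not
  increase with $\sigma$ over $\{0.1, 0.3, 0.6\}$, and equals 1 across
  AHP, BWS and cards in the noiseless limit. The recovery runs disable CR
  screening so that the measured degradation is attributable to judgment
  noise alone rather than to cohort attrition (at high $\sigma$ a strict
  threshold can exclude nearly everyone).

Problem sizes (300 coverage replicates, 100 recovery replicates per noise
level, 1000-matrix oracle sweeps) were chosen so that Monte-Carlo error is
small relative to the tolerance being checked while the whole suite stays
comfortably interactive.

## Worked example

```{r example, eval = FALSE}
library(prefrank)

h <- info_hierarchy()
cfg <- synthetic_config(hierarchy = h, seed = 1)   # 39 respondents
sim <- simulate_study(cfg)

fit <- ahp(sim$judgments, h, mode = "AIP", central = "geometric",
           cr_threshold = 0.1)
print(fit)
summary(fit)

bfit <- bws(sim$bws_choices, sim$bws_design)
method_comparison(fit, bfit, cards = sim$cards)
ahp_bws_tau(fit, sim$bws_choices, sim$bws_design)

bt <- ahp_boot(fit, B = 1000, seed = 1)
rank_stability(bt)$robust
```

## Known limitations

* The AIP "group CR" is a diagnostic of our own construction; different
  published constructions exist and none is standard.
* The exact standardization behind published BWS value tables is rarely
  stated; only the per-block 0–1 rescaling is inferable, and that is what
  we make canonical.
* Incomplete respondents are reported and excluded, never imputed; no
  incomplete-matrix completion is attempted.
* Alternative-addition/deletion rank reversal (the classical AHP
  criticism) is out of scope: the designs this package serves have no
  alternatives level.
* Respondent weighting is equal; consensus-building or
  compatibility-index methods are not implemented.
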