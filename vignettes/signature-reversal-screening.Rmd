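---
title: "Methods: signature-reversal screening and combination-index analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature-reversal screening and combination-index analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connscreen)
```

# Overview

`connscreen` implements two linked analyses. The *screening arm* asks, for a
collection of drug-treatment expression profiles and an up/down query gene
signature, which drugs consistently reverse (or mimic) the query state; it
is the computational core of connectivity-map-style repurposing screens for
agents that oppose, e.g., a cancer-stem-cell-like expression program. The
*synergy arm* quantifies whether two drugs combine super-additively in
viability assays, using the median-effect model and the combination index.

This vignette records the models, their assumptions, the tunable parameters,
and the numerical and design choices the implementation makes where the
methodology leaves room.

# The screening model

## Robust z-scores

Raw profile intensities are converted per gene (across all profiles of the
collection) to robust z-scores,

$$ z = \frac{x - \mathrm{median}(x)}{1.4826 \cdot \mathrm{MAD}(x)} , $$

with $\mathrm{MAD}$ the unscaled median absolute deviation; 1.4826 is the
usual consistency constant that makes the denominator estimate a standard
deviation under normality. Genes with zero MAD get a floor of $10^{-9}$ (so
ties at the median score exactly 0) and a warning — such genes carry no
ranking information, and the floor merely keeps the division defined.
Z-scoring is done across the full collection rather than per plate: the
package has no notion of plate structure, and robust statistics keep a
handful of strong responders from distorting a gene's scale.

## The signed KS connectivity statistic

For one profile, genes are ranked by z descending (ties broken by ascending
gene id — determinism matters more than any particular tie order, and ties
are rare in continuous data). Each signature side with tag ranks
$V(1) < \dots < V(t)$ among $n$ genes is scored

$$ a = \max_j\left[\tfrac{j}{t} - \tfrac{V(j)}{n}\right], \qquad
   b = \max_j\left[\tfrac{V(j)}{n} - \tfrac{j-1}{t}\right], \qquad
   ks = \begin{cases} a & a > b \\ -b & \text{otherwise,} \end{cases} $$

the classic signed Kolmogorov–Smirnov enrichment form: $ks > 0$ when the
tags pile toward the top of the ranking. The raw connectivity combines the
two sides, $s = ks_{up} - ks_{down}$, **only when their signs differ**; when
both tag sets concentrate at the same end the profile carries no coherent
directional signal and $s = 0$. This zero rule is not an implementation
nicety — under a null profile the two sides agree in sign about half the
time, so zeros are a substantial, expected part of the score distribution,
and they propagate to the drug level (see *Calibration* below).

Scaled scores divide positive $s$ by the collection maximum $p$ and negative
$s$ by $|q|$, the magnitude of the collection minimum, giving
$c \in [-1, 1]$ with an endpoint attained whenever any score is non-zero.
Both $s$ and $c$ are reported, since either may be wanted downstream.

A screen for *reversers* scores profiles against the query with its sides
swapped (`reverse_query = TRUE`), so that reversing profiles receive
positive $c$ and rise to the top of the ranking. The polarity is a flag, not
hard-coded, because both directions are legitimate queries (a mimicker
screen is the same computation).

## Drug-level enrichment

Profiles are ordered by $c$ (descending, ties by profile id) and each drug's
profiles form a hit set of size $N_h$ in a list of $N$. The running sum
accumulates $|c_i|^w / N_R$ at hits ($N_R = \sum_{hits} |c|^w$) and
$1/(N - N_h)$ at misses; the enrichment score is the signed extreme
deviation, with the positive extreme winning exact magnitude ties. The
default weight is $w = 1$, the standard weighted form, which has the useful
side effect that zero-connectivity profiles contribute no hit mass; $w = 0$
(classic KS, positions only) is available.

The null is a *set-label permutation*: random hit sets of size $N_h$ drawn
without replacement, ES recomputed, 1000 draws by default. Because the null
depends only on the ranked metric and $N_h$, one null is computed per
distinct hit-set size and shared by all drugs of that size — statistically
identical to per-drug nulls and much cheaper. Normalization is
sign-stratified, $NES = ES / \overline{|ES^*|}_{\text{same sign}}$, and the
p-value uses the add-one rule
$(1 + \#\{|ES^*| \ge |ES|,\ \text{same sign}\}) / (1 + \#\text{same sign})$,
which never returns exactly zero. Conventions for degenerate cases are
fixed and deliberate: $ES = 0$ (a drug whose profiles all have $c = 0$)
reports $NES = 0$, $p = 1$; an ES whose sign never appears in the null
reports a signed infinite NES with $p = 1/(n_{perm}+1)$.

## Calibration

With no planted signal, the p-values of drugs with a non-degenerate hit set
are uniform — the validation suite checks this with a Kolmogorov–Smirnov
test at the study scale (100 drugs × 3 replicates, 978 genes, 1000
permutations). Drugs whose replicates *all* score zero connectivity — under
the null roughly $(1/2)^3$ of three-replicate drugs, a direct consequence
of the same-sign zero rule — sit at the conservative sentinel $p = 1$ by
the convention above. Strict uniformity over all drugs therefore cannot
hold, by construction: the test suite checks uniformity conditionally on a
non-degenerate hit set, and separately that the degenerate drugs really do
carry $p = 1$. For inference this point mass is harmless (it is
conservative), but consumers ranking by p-value should expect a block of
ties at 1.

# The synthetic collection

`make_collection()` emulates a landmark-gene profile collection: 978 genes,
100 drugs × 3 replicate profiles by default, i.i.d. $N(0, \sigma)$ z-score
background with $\sigma = 1$ — the natural null for data that are
themselves robust z-scores. The query signature (100 up + 100 down tags by
default, a conventional query size) is drawn from the gene universe, and
each replicate profile of a planted reverser shifts its up tags by
$-\delta$ and down tags by $+\delta$ (mimickers: flipped). A mean shift was
chosen over, say, rank surgery because it makes the reversal strength a
single interpretable scalar in z-units.

What the generator does *not* emulate: plate and batch structure,
gene–gene correlation, heavy-tailed or skewed profile populations,
cell-line-specific baselines, and dose- or time-dependence of the
perturbation. Passing recovery tests on this background therefore
demonstrates the statistical machinery — scoring, ranking, permutation
inference — under a clean null, not robustness to the artefact structure of
real collections. With $\delta = 1.5$, 3 replicates and a 100+100 signature,
the planted reverser's profiles saturate the top of the connectivity
ranking and the screen recovers it at rank 1; the test suite asserts
this over 20 seeds.

# The synergy model

## Median-effect fits

The median-effect equation $f_a/f_u = (D/D_m)^m$ log-linearises to
$\log_{10}(f_a/(1-f_a)) = m\,\log_{10} D - m \log_{10} D_m$; the fit is
ordinary least squares on that scale, $m$ the slope, $D_m = 10^{-\beta_0/m}$
(the IC50 under this model), and $r$ the correlation of the line. Replicates
are averaged *in fa space per dose* before the transform — transforming
first and averaging after would bias the fit where noisy values approach 0
or 1. Fraction-affected values are clamped to $(10^{-6}, 1-10^{-6})$ because
the logit transform is undefined at the endpoints. A response with no
gradient (identical fa at all doses) is an error; a fitted $m \le 0$
(non-cytotoxic trend) is returned but flagged invalid with a warning.

The synthetic dose design is an 8-point $\sqrt2$-fold dilution series
centred on $D_m$, keeping noiseless fa within roughly 0.2–0.8. That is the
conventional informative design for median-effect work: outside it the
logit's derivative $1/(f_a(1-f_a))$ inflates assay noise (default
$\sigma_{fa} = 0.02$, typical triplicate viability scatter) several-fold
and the fit degrades sharply. With this design the test suite
recovers $(m, D_m) = (1.2, 2)$ within 5% in at least 95 of 100 seeds.

## Combination index

For a dose pair $(d_1, d_2)$ with observed combined effect $f_a$,

$$ CI = \frac{d_1}{D_{x1}(f_a)} + \frac{d_2}{D_{x2}(f_a)},
   \qquad D_{xi}(f_a) = D_{mi}\left(\frac{f_a}{1-f_a}\right)^{1/m_i} , $$

the two-term mutually exclusive form, which is the standard reported CI;
the three-term mutually nonexclusive variant (adding
$d_1 d_2 / (D_{x1} D_{x2})$) is available behind a flag but off by default.
CI < 1 is called synergism and CI > 1 antagonism; because an exact CI = 1
never occurs in noisy data, the additive call uses a band of ±0.05 around 1.
Combinations are summarised as mean CI ± sample SD across dose pairs (one
point has SD reported as 0 and flagged undefined).

The combination generator inverts the same structure: it solves
$d_1/D_{x1}(f_a) + d_2/D_{x2}(f_a) = \gamma$ for $f_a$ (the left side is
strictly decreasing in $f_a$, so the root is unique; found by bisection to
$10^{-12}$), making the interaction strength $\gamma$ an identifiable
ground-truth parameter: noiseless data give back $CI = \gamma$ at every
pair exactly, and noisy data ($\sigma_{fa} = 0.02$) give mean CI within 10%
of $\gamma$ across the default five-pair design in the validation runs.

# Numerical conventions, in one place

- Gene-rank ties → ascending gene id; profile-metric ties → ascending
  profile id (reproducibility over any statistical rationale).
- ES extreme ties → positive side reported.
- fa clamp bound $10^{-6}$; MAD floor $10^{-9}$; combination root tolerance
  $10^{-12}$.
- Permutation p-values use add-one smoothing; minimum reportable p is
  $1/(n_{perm}+1)$.
- All seeded generators restore the caller's RNG state; identical seeds
  give bit-identical outputs, and the pipeline writers format numbers at
  fixed precision (`%.15g`) so reruns are byte-identical files.

# Problem sizes used by the test suite

The validation suite runs the screen at the full study geometry (978 genes,
100 drugs × 3 replicates, 1000 permutations) — single screens take well
under a second — with 20 seeds for recovery and one seed for calibration;
oracle-equivalence checks use 200 random instances per statistic; the
synergy recovery loops use 100 seeds of 8-dose × 3-replicate plates. These
sizes were chosen as the smallest at which the claimed rates (18/20,
95/100) are meaningful proportions.

# Known limitations

- The screen implements the classic rank-based KS connectivity form, not
  later weighted-connectivity or multi-cell-line aggregation schemes.
- No multiple-testing correction across drugs or signatures is applied;
  the screen reports per-drug permutation p-values only.
- Median-effect fitting is unweighted least squares on the logit scale;
  no confidence intervals on $m$, $D_m$ or CI are computed.
- The synthetic background is independent-normal; conclusions about
  behaviour on correlated real profile collections require real data.
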