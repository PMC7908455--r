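---
title: "Quantitative SWOT-AHP analysis: model, conventions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative SWOT-AHP analysis: model, conventions, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swotahp)
```

## The model

A SWOT analysis sorts the decision environment into internal strengths (S)
and weaknesses (W) and external opportunities (O) and threats (T). On its
own it is qualitative; this package implements the standard quantification
that couples it with the analytic hierarchy process (AHP) and a strategic
vector summary. The pipeline has three stages.

**1. Within-group AHP weights.** For each group, experts compare every pair
of factors on the Saaty scale — 1 (equal importance) to 9 (extreme
importance) and their reciprocals — giving a positive reciprocal judgment
matrix $A = (a_{ij})$ with $a_{ii} = 1$ and $a_{ij} a_{ji} = 1$. Priorities
are estimated by the product-square-root (row geometric mean) method:

$$\bar W_i = \Big(\prod_{j=1}^n a_{ij}\Big)^{1/n}, \qquad
  W_i = \bar W_i \Big/ \sum_j \bar W_j .$$

For a perfectly consistent matrix ($a_{ij} = w_i / w_j$) this recovers $w$
exactly, and at order 3 it coincides with the principal-eigenvector method
(both facts are verified by the test suite). Consistency of the judgments is
diagnosed through the eigenvalue estimate

$$\lambda_{\max} = \frac{1}{n} \sum_i \frac{(A W)_i}{W_i}, \qquad
  CI = \frac{\lambda_{\max} - n}{n - 1}, \qquad CR = CI / RI,$$

with $RI$ the expected $CI$ of random reciprocal matrices of the same order
(`saaty_ri()`, orders 1–10: 0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45,
1.49). A matrix is accepted when $CR < 0.1$. For $n \le 2$ a reciprocal
matrix is always consistent, so $CR$ is defined as 0 and passes. For
$n > 10$ the package refuses unless the user supplies an extended RI table;
random-index values beyond order 10 differ between published tabulations, so
none is baked in.

**2. Signed intensities.** Each factor also carries an *estimated strength*,
its actual magnitude on a 0–5 scale. A factor's intensity is
$\text{strength} \times \text{weight}$, signed by group membership: positive
for S and O, negative for W and T. Strengths are accepted as non-negative
magnitudes and the sign is applied by the package; inputs that arrive
pre-signed for W/T factors are normalised to magnitudes with a warning, since
both conventions occur in published tables. Strengths need not be integers
(a strict check is available via the config's factor validation); group
weights must sum to 1, so each group total is a convex combination of
strengths and its magnitude can never exceed 5.

**3. The strategic vector.** The four signed group totals are drawn on four
semi-axes (S: $+x$, W: $-x$, O: $+y$, T: $-y$), forming the strategic
quadrilateral. Its centroid $P(X, Y)$ with $X = (\Sigma S + \Sigma W)/4$,
$Y = (\Sigma O + \Sigma T)/4$ gives the strategic azimuth
$\theta = \operatorname{atan2}(Y, X)$ mapped to $[0°, 360°)$. The positive
and negative strategic intensities are $U = |\Sigma O| \cdot |\Sigma S|$ and
$V = |\Sigma T| \cdot |\Sigma W|$, and the intensity coefficient is
$\rho = U / (U + V) \in [0, 1]$.

Two conventions here were genuinely open and are package design choices:

* The azimuth is often written as a single-argument arctangent of $Y/X$ with
  range $[0, \pi]$, which cannot separate quadrants I/III or II/IV. The
  two-argument form is used instead; it agrees with the single-argument form
  whenever $Y \ge 0$ and supports all four strategy quadrants, which the
  classification requires.
* $U$ and $V$ are defined on magnitudes. Multiplying the *signed* totals
  would make $V$ negative whenever exactly one of $\Sigma T$, $\Sigma W$ is
  nonzero-negative, and $\rho$ could leave $[0, 1]$; magnitudes keep both
  intensities non-negative, matching how such values are reported in
  practice.

**Strategy call.** The centroid quadrant names the strategy — SO (growth),
WO (turnaround), WT (defensive), ST (diversification) — and $\rho > 0.5$
splits each into aggressive versus conservative. Published treatments of the
spectrum rarely state sub-thresholds beyond the quadrants, so only this
quadrant-plus-$\rho$ taxonomy is implemented; a centroid on an axis is
reported as a boundary case naming both adjacent types rather than silently
picking one, and a centroid at the origin yields a boundary call with an
explanatory note.

## Precision: the `digits` chain

`run_full_analysis()` takes a `digits` argument (default 4) that controls a
*stage-rounding* chain: the row geometric means are rounded half away from
zero to `digits` decimals before normalisation, the weights before the
intensity products, $\lambda_{\max}$ before $CI$, the group totals before
the centroid, the centroid before $\theta$, and $U$, $V$ before $\rho$.
Angles are reported to 2 decimals, everything else to `digits`.

This emulates the fixed-precision desk arithmetic behind published AHP
tables, and it is what makes the bundled case study reproduce digit for
digit: at full double precision the third opportunity weight is 0.691(0),
the opportunity total 4.2905 and the azimuth 53.11°, while the
fixed-precision chain yields the tabulated 0.6909, 4.2901 and 53.09°. The
differences are all in the last printed digit and never change the strategy
call (the suite asserts agreement of the two chains to within 5 units of the
4th decimal). Set `digits = NULL` for full-precision research use. Rounding
is half away from zero (`round_half_away()`), the convention of such tables,
not banker's rounding; a small guard lifts binary doubles sitting just under
a decimal half onto it, so 0.18315 rounds to 0.1832.

## The synthetic expert-panel generator

`generate_panel()` and `generate_swot_config()` exist so that every pipeline
stage is testable without external data. The elicitation model is
multiplicative log-normal noise: each upper-triangle judgment of the
consistent ratio matrix $a_{ij} = w_i / w_j$ is multiplied by
$\exp(\varepsilon)$, $\varepsilon \sim N(0, \sigma^2)$ i.i.d., and the lower
triangle is rebuilt from reciprocals. This is the standard error model for
reciprocal matrices: it is sign-safe, keeps reciprocity exact, and makes
$\sigma = 0$ the perfectly consistent limit. Optional quantization snaps
each noisy judgment to the nearest Saaty value *in log space* (the scale is
approximately geometric, so log distance is the right metric); ties —
e.g. $\sqrt 2$, equidistant between 1 and 2 — resolve toward 1, the
conservative "equal importance" end. Snapping is idempotent.

Seeding is a single master seed from which per-expert (and per-group)
sub-seeds are drawn deterministically, so a seeded panel or config is fully
reproducible and written configs are byte-identical across runs. Synthetic
true weights are independent standard-exponential draws normalised to sum 1
(a flat Dirichlet — symmetric, no group structure), and strengths are
uniform integers on 0..5, mirroring how strengths are assigned in practice.
Default noise is $\sigma = 0.2$, which keeps order-3/4 matrices essentially
always below the $CR < 0.1$ gate while being clearly non-trivial; the
simulation script `analysis/02_panel_simulation.R` tabulates mean $CR$
against $\sigma \in \{0, 0.1, 0.2, 0.4\}$ (100 replicates per level) and the
L1 weight-recovery error against panel size at $\sigma = 0.3$, sizes chosen
to run in seconds.

What the generator does *not* emulate: expert bias structures (anchoring,
halo effects, systematic optimism of a stakeholder group), incomplete
pairwise designs, or correlation between judgments and strengths. Passing
tests on synthetic panels therefore demonstrate the estimator's and
aggregator's correctness under honest independent noise, not robustness to
structured disagreement among real experts.

## Aggregation convention

When several experts each supply a matrix, `aggregate_judgments()` combines
them by the element-wise geometric mean (aggregation of individual
judgments, AIJ) — the only aggregation rule that preserves reciprocity by
construction. Published studies that report a single matrix per group often
leave the panel-to-matrix step unstated; the bundled case-study matrices are
therefore treated purely as inputs, and AIJ is offered as the documented
convention for users with raw panels.

## Degenerate and edge inputs

* All-zero strengths give all-zero totals; the quadrilateral is flagged
  degenerate, $\rho$ is undefined ($U + V = 0$) and the analysis stops with
  a dedicated error rather than returning a meaningless call.
* The reciprocity tolerance defaults to $10^{-6}$ on $|a_{ij} a_{ji} - 1|$;
  survey matrices transcribed at limited precision can loosen it in the
  config options.
* Judgments outside the literal 17-value Saaty set (e.g. 3.5, or aggregated
  panel values) warn by default and error under `strict_saaty`.
* The CR gate on `run_full_analysis()` errors by default and is demotable to
  a warning (`cr_gate = "warn"`), for exploratory use on inconsistent
  panels.

## Problem sizes and limitations

The bundled study (13 factors, matrices of order 3–4) runs in well under a
second; the property and simulation checks use orders 2–9, panels up to 200
experts and 100 replicates per noise level, all chosen to complete in
seconds while leaving the Monte-Carlo conclusions stable under the fixed
seeds. Known limitations: a single AHP level per group (no group-level
comparison matrix layer), no alternative prioritisation methods (eigenvector
as primary, fuzzy AHP), no rank-reversal analysis, and no
sensitivity/tornado decomposition of the strategy call beyond the panel
resampling offered by the synthetic module.
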