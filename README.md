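# swotahp

Quantitative SWOT analysis with AHP weighting and strategic vectors.

A plain SWOT analysis lists strengths (S), weaknesses (W), opportunities (O)
and threats (T) but says nothing about how much each matters. `swotahp`
implements the standard SWOT-AHP quantification used in strategic planning
and public-health policy analysis: expert pairwise comparisons on the Saaty
scale give within-group priority weights, 0–5 estimated strengths turn the
weights into signed intensities, and the four group totals are summarised as
a strategic vector that names the recommended strategy type. It is aimed at
analysts who have (or want to simulate) expert judgment matrices and need
the whole chain — validation, consistency diagnostics, intensities,
strategy call, reports and figures — reproducibly in one place.

## The model

For each group, a positive reciprocal judgment matrix $A = (a_{ij})$ on the
Saaty 1/9…9 scale is reduced to weights by the product-square-root method,

$$\bar W_i = \Big(\textstyle\prod_j a_{ij}\Big)^{1/n},\qquad
  W_i = \bar W_i / \textstyle\sum_j \bar W_j,$$

and checked for consistency via
$\lambda_{\max} = \frac1n \sum_i (AW)_i / W_i$,
$CI = (\lambda_{\max}-n)/(n-1)$, $CR = CI/RI$, accepting the matrix when
$CR < 0.1$. Factor intensity is $\text{strength} \times W_i$, positive for
S/O and negative for W/T. The four group totals, drawn on four semi-axes,
form the strategic quadrilateral; its centroid
$P\big((\Sigma S+\Sigma W)/4,\ (\Sigma O+\Sigma T)/4\big)$ gives the azimuth
$\theta = \operatorname{atan2}(Y, X)$, and
$U = |\Sigma O||\Sigma S|$, $V = |\Sigma T||\Sigma W|$,
$\rho = U/(U+V)$ measure how strongly the positive side dominates. The
centroid quadrant names the strategy (SO / WO / WT / ST) and $\rho > 0.5$
marks it aggressive rather than conservative.

A synthetic expert-panel generator (log-normal judgment noise, optional
Saaty quantization, geometric-mean aggregation) makes every stage testable
without external data. See `vignette("swot-ahp-methods")` for conventions
and numerical choices.

## Worked example

The package ships a complete case study — the development strategy of
home-based exercise in China, 13 factors across the four groups — as a YAML
fixture:

```r
library(swotahp)
res <- run_full_analysis(load_config(home_exercise_path()))
print(res)
```

```
Group W  (lambda_max 3.1078, CI 0.0539, CR 0.0929, consistent)
  W1   weight 0.2184  strength 3  intensity  -0.6552
  W2   weight 0.1515  strength 2  intensity  -0.3030
  W3   weight 0.6301  strength 4  intensity  -2.5204
  total intensity -3.4786
...
Totals: S 4.2112, W -3.4786, O 4.2901, T -3.3144
Strategic vector: centroid (0.1832, 0.2439), theta = 53.09 deg,
  U = 18.0665, V = 11.5295, rho = 0.6104
Strategy call: SO, aggressive (theta = 53.09 deg, rho = 0.6104)
```

Every comparison matrix passes the consistency check (largest CR 0.0929 <
0.1), so the weights are trustworthy. Opportunities carry the largest total
intensity (4.2901), strengths are close behind (4.2112), and both negative
totals are smaller in magnitude — the centroid falls in the first quadrant
(θ ≈ 53°) with ρ = 0.6104 > 0.5, so the supported call is an aggressive SO
(growth) strategy: pair internal strengths with external opportunities.

`write_report()` serialises the result as diffable JSON or as Markdown
tables; `render_plots()` draws the strategic quadrilateral and the polar
strategy spectrum. The scripts under `analysis/` run the case study
(`01_reproduce_study.R`) and a simulation study of noise, panel size and
call robustness (`02_panel_simulation.R`), writing tables and figures to
`results/`.

Analyses default to `digits = 4`: each stage consumes the previous stage's
values rounded to 4 decimals, the fixed-precision arithmetic that published
AHP tables contain (use `digits = NULL` for full double precision — results
differ only in the last decimal).

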