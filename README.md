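# rsmval

Response-surface method development and 2002/657/EC validation statistics
for targeted multi-residue LC-MS/MS quantification.

When a multi-residue method (here: a 43-compound quinolone/sulfonamide
panel in cured pork matrices) is developed with a QuEChERS-style clean-up,
the dispersive-SPE sorbent masses are tuned with a designed experiment and
the finished method is validated against the European Commission Decision
2002/657/EC criteria. `rsmval` implements that computational chain as
composable, tested R functions:

* **Design of experiments** — three-factor Box–Behnken designs
  (`bbd_design()`, 12 edge runs + replicated centers) with exact
  coded/actual unit mapping (`bbd_factor()`, `coded_to_actual()`).
* **Response-surface modelling** — `rsm_fit()` fits the full second-order
  polynomial
  `Y = b0 + Σ bj xj + Σ bij xi xj + Σ bjj xj²`
  to the per-run compliant-analyte count by QR least squares, with the
  standard methods (`print`, `summary`, `coef`, `predict`, `residuals`,
  `fitted`, `anova`, `plot`, `simulate`). `rsm_anova()` produces the
  Type-III table (`SSj = βj² / [(X'X)⁻¹]jj`) including the lack-of-fit /
  pure-error split; `adequacy_stats()` gives R², adjusted and predicted R²
  (PRESS), and adequate precision. Both also work from a coefficient-only
  equation plus aggregate sums of squares, so a published ANOVA can be
  reconstructed without the raw runs.
* **Optimization** — `stationary_point()` classifies the surface;
  `optimize_surface()` maximizes it exactly over the coded cube by
  recursive face restriction (no iterative optimizer);
  `confirmation_check()` scores confirmation runs.
* **2002/657/EC validation** — `cc_limits()` (CCα = 0.2·VL + 1.64·SD,
  CCβ = CCα + 1.64·SD), `matrix_effect()` (slope-ratio ME with the ±50%
  classification), `loq_estimate()` (concentration at S/N = 10),
  `compliant_count()` (the 80–110% recovery window), and
  `validation_summary()` assembling recovery, intra-/inter-day precision,
  linearity, CCα/CCβ, ME and LOQ per analyte × matrix.
* **Synthetic experiments** — `synthetic_truth()` plus
  `simulate_recovery_experiment()` / `simulate_quant_assets()` generate
  seeded spiked-recovery and calibration data with the study's replicate
  structure; `construct_consistent_response()` builds response vectors
  that refit *exactly* to a given equation with a prescribed
  residual/pure-error split.
* **Pipeline & I/O** — `read_tables()` (validated CSV schemas),
  `write_design()`, and `run_pipeline()` for a seed-deterministic
  end-to-end run with a JSON report.

## Worked example

```r
library(rsmval)

des  <- bbd_design(c("A", "B", "C"))      # 17-run BBD, 5 centers
surf <- sorbent_surface_example()         # bundled reference equation
y    <- construct_consistent_response(surf, 11.3, 2.8, des, seed = 1)
fit  <- rsm_fit(des, y)
anova(fit)
```

```
Analysis of variance (Type-III partial SS)
      Source Sum Sq Df Mean Sq F value  Pr(>F)
       Model  737.8  9   81.97   50.78 <0.0001 **
           A      2  1       2   1.239  0.3024
           B     18  1      18   11.15  0.0124  *
           C   60.5  1    60.5   37.48  0.0005 **
         ...
    Residual   11.3  7   1.614
 Lack of fit    8.5  3   2.833   4.048  0.1051
  Pure error    2.8  4     0.7
   Cor total  749.1 16   46.82
```

The model is highly significant (F = 50.78), the lack of fit is not
(p = 0.105), and each factor's partial SS shows Z-Sep+ (C) dominating the
linear effects. Adequacy and the optimum:

```r
adequacy_stats(fit)
#>   R-squared        0.9849
#>   Adjusted R-sq    0.9655
#>   Predicted R-sq   0.8126   (PRESS 140.4)
#>   Adeq precision   19.293   (> 4 adequate)

optimize_surface(fit)
#> Optimum over the coded region:
#>   coded   : -0.0595 -0.0875 -0.4844
#>   predicted response 42.5466; count 42 (rounding: truncate)
```

The fitted surface has an interior maximum: about 42.5 — i.e. 42 — of the
43 analytes are predicted compliant at the optimal sorbent blend, and a
set of confirmation runs is scored with
`confirmation_check(42.55, c(42, 43, 43, 43, 43))` (mean 42.8, RSD 1.0%).

Validation metrics from a simulated panel:

```r
truth <- synthetic_truth(seed = 1)
qa    <- simulate_quant_assets(truth)
vs    <- validation_summary(qa$replicates_02vl, qa$curves)
head(vs$analytes[, c("analyte", "cc_alpha", "cc_beta", "me", "me_class")])
```

`cc_alpha` sits a little above 10 µg/kg (0.2 × VL plus 1.64 replicate
SDs) and `cc_beta` the same distance above `cc_alpha`, mirroring how the
decision limit and detection capability are reported in practice.

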