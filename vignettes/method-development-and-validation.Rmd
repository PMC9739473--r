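---
title: "Response-surface optimization and 2002/657/EC validation of multi-residue LC-MS/MS methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Response-surface optimization and 2002/657/EC validation of multi-residue LC-MS/MS methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsmval)
```

## The problem

Developing a multi-residue veterinary-drug method for a fatty matrix such
as cured pork means tuning the dispersive-SPE clean-up — here the masses of
three sorbents, C18, PSA and a zirconia-coated silica (Z-Sep+) — so that as
many analytes as possible are recovered within the regulatory window, and
then demonstrating, analyte by analyte, that the method satisfies the
European Commission Decision 2002/657/EC performance criteria. This
package implements that computational chain: the experimental design, the
response-surface model and its diagnostics, the constrained optimization of
the fitted surface, and the validation statistics, together with a seeded
generator of synthetic spiked-recovery experiments so that every stage can
be exercised and tested without instrument data.

## The design and the response

A three-factor Box-Behnken design places runs at the midpoints of the
edges of the factor cube — all $(\pm 1, \pm 1)$ combinations over each
factor pair with the third factor at its center — plus replicated center
points: $12 + n_c$ runs. With the default $n_c = 5$ the design has 17 runs
and 16 total degrees of freedom, of which 4 are pure error. Factor levels
are coded by the affine map $x = (\text{actual} - \text{center}) /
\text{half-range}$; only symmetric codings are accepted, so the map is
exactly invertible. The canonical run order (pairs (A,B), (A,C), (B,C),
each in $(-,-),(-,+),(+,-),(+,+)$ order, centers last) is fixed: run-order
randomization matters at the bench but changes none of the statistics
computed here.

The response $Y$ is a *count*: the number of analytes whose mean recovery
at that run falls inside the compliance window (80--110% by default,
endpoints included; `compliant_count()`). A count is integer-valued, but
the fitted surface treats it as continuous — the usual response-surface
approximation.

## The model, its ANOVA and its adequacy

`rsm_fit()` fits the full second-order polynomial

$$Y = b_0 + \sum_j b_j x_j + \sum_{i<j} b_{ij} x_i x_j + \sum_j b_{jj} x_j^2$$

by QR-based least squares on the 10-column coded model matrix. The ANOVA
(`rsm_anova()`) uses Type-III (partial) sums of squares,
$SS_j = \hat\beta_j^2 / [(X'X)^{-1}]_{jj}$, which for this design are
$8 b_j^2$ for linear terms, $4 b_{ij}^2$ for interactions and
$b_{jj}^2 / 0.2375$ for quadratics — the convention of standard DoE
software, so published tables can be reconstructed from a printed equation
alone. Two points are worth knowing:

* The intercept/quadratic block of $X'X$ is not diagonal (every $x_j^2$
  column has the same eight nonzero entries), so the nine partial SS do
  **not** add up to the model SS; the model SS is computed directly from
  the fitted values and the identity $SS_{model} + SS_{res} = SS_{tot}$
  holds instead.
* The residual is split into pure error (variation among replicated
  points — the centers) and lack of fit; their ratio of mean squares is
  the lack-of-fit F test. On a design without replicates the residual is
  all lack of fit and a warning is issued.

Significance flags follow the thresholds `**` for $p<0.01$ and `*` for
$p<0.05$, applied uniformly from the computed p-values.

`adequacy_stats()` reports $R^2$, adjusted $R^2$, PRESS and predicted
$R^2$ (leave-one-out via $e_i/(1-h_{ii})$, so the raw response is needed),
and adequate precision $(\max\hat y - \min\hat y)/\sqrt{p\,MS_{res}/n}$
over the design points with $p = 10$; values above 4 are conventionally
taken as an adequate signal-to-noise ratio. Both `rsm_anova()` and
`adequacy_stats()` accept either a fitted model or a coefficient-only
surface plus aggregate sums of squares — the latter is how a published
table is reproduced when the raw runs were not published; predicted $R^2$
is then reported as unavailable rather than guessed.

## Optimization

`stationary_point()` solves $\nabla Y = 0$ (Hessian $H_{jj} = 2 b_{jj}$,
$H_{ij} = b_{ij}$) and classifies the point by eigenvalue signs with a
relative zero tolerance of $10^{-8}$; a singular Hessian raises a
condition carrying the null direction. `optimize_surface()` maximizes the
quadratic over the coded cube *exactly* by recursive restriction: the
interior stationary point is one candidate, and fixing any coordinate at a
bound induces a lower-dimensional quadratic that is treated the same way,
down to the vertices. In three dimensions this enumeration is cheap and
avoids any iterative-optimizer tolerance; ties are broken toward the
lexicographically smallest coordinates. The continuous optimum of a count
surface is converted to a predicted count by truncation toward zero by
default — a surface maximum of 42.5 analytes means 42 analytes can be
expected to comply — with `"nearest"` and `"none"` selectable.
`confirmation_check()` then compares replicate confirmation runs with the
prediction (mean, sample-SD-based RSD%, absolute deviation).

For the bundled reference equation the stationary point is interior at
coded $(-0.060, -0.088, -0.484)$ with all Hessian eigenvalues negative and
a predicted response of about 42.5; the tests verify this against an
independent dense-grid search with step 0.01.

## Validation statistics

For analytes without a maximum residue limit, validated at a level
$VL = 50\ \mu g/kg$ with spikes at $0.1,\ 0.2,\ 1 \times VL$:

* **Decision limit / detection capability** (`cc_limits()`):
  $CC\alpha = 0.2\,VL + 1.64\,SD$ and $CC\beta = CC\alpha + 1.64\,SD$,
  where $SD$ is the standard deviation of measured concentrations at the
  $0.2 \times VL$ spike, pooled across days (the pooling convention is a
  package choice; the replicate structure is 6 per day over 3 days). The
  spacing identity $CC\beta = 2\,CC\alpha - 0.2\,VL$ is exact and is what
  makes a published table internally checkable to its rounding precision.
* **Matrix effect** (`matrix_effect()`):
  $ME = (S_{mat}/S_{sol} - 1)\times 100$ from the matrix-matched and
  solvent calibration slopes (ordinary least squares; weighting is out of
  scope). $|ME| \le 50$ is classed mild-or-medium, beyond that strong; the
  boundary belongs to mild-or-medium.
* **LOQ** (`loq_estimate()`): the concentration at signal-to-noise 10,
  scaled linearly from a reference measurement, $10 \cdot c / (S/N)$. (A
  literal product of 10 and an S/N ratio is dimensionless and cannot be a
  concentration; the linear-scaling definition is the meaningful one.)
* **Precision** (`validation_summary()`): intra-day RSD is the pooled
  (root-mean-square) within-day RSD; inter-day RSD is the RSD of all
  replicates across days. All-replicates pooling, rather than the RSD of
  day means, is the convention adopted where the choice is unstated in
  regulatory practice.
* **Linearity**: matrix-matched calibration passes at $R^2 > 0.99$.

Missing inputs are reported as `NA`, never defaulted: an analyte without a
$0.2 \times VL$ level gets no $CC\alpha/CC\beta$.

## The synthetic-data generator

`synthetic_truth()` defines a data-generating process that mirrors the
structure the analysis assumes: each analyte in a 43-compound panel has a
quadratic true-recovery surface over the coded factors, and measurements
are the spike times recovery with multiplicative Gaussian noise. The
defaults are the study conditions, chosen once:

| parameter | default | rationale |
|---|---|---|
| panel size | 43 | the reference multi-residue panel |
| baseline recovery | uniform 88--106% | centers the panel inside the 80--110% window with a realistic spread |
| curvature | normal, mean $-8$, SD 3 (% per coded$^2$) | recovery degrades toward the region edges, so the compliant count drops from ~42 at the center to ~20 at corners, the dynamic range a clean-up optimization actually shows |
| linear / interaction terms | normal, SD 2 / 1 | mild per-analyte asymmetry |
| noise CV | 8% | mid-range of typical intra-day RSDs ($\le$ 10.7%) |
| SD at $0.2\times VL$ | 0.55 $\mu$g/kg | the low end of the reference decision-limit table (inverting $CC\alpha = 10.9$ gives 0.549) |
| replicate structure | 3 per design run; 6 $\times$ 3 days at $0.2\,VL$ | triplicate optimization runs; standard precision design |

With these settings the simulated center-point counts have a pure-error
mean square close to 0.7 — the scale of the reference experiment — without
any per-quantity tuning. Every generator is a pure function of its
parameters and a seed.

`construct_consistent_response()` solves a different problem: given a
*published* equation and aggregate ANOVA, it builds a response vector
$y = X\beta + e$ with $e$ orthogonal to the model space, its center-
contrast component carrying exactly the pure-error SS and the remaining
lack-of-fit component the rest. Refitting returns the published
coefficients to machine precision and the full ANOVA reproduces the
published rows; the direction of $e$ within each subspace is randomized by
the seed, so infinitely many raw datasets consistent with the published
summary can be generated.

### What passing tests do and do not show

The generator's recovery surfaces are exactly quadratic, its noise is
Gaussian and multiplicative, and its calibration curves are exactly linear
apart from a small CV. Real spiked-recovery data have analyte-specific
noise, occasional gross outliers, heteroscedastic calibration, and a
compliant-count surface that is a sum of step functions — only
approximately quadratic. Tests passing on the synthetic conditions
therefore demonstrate the *computations* (design geometry, partial SS,
exact cube optimization, estimator algebra) and reasonable statistical
behaviour under the assumed model; they do not certify performance on any
particular instrument's data. The parameter-recovery property quantifies
one aspect of this: across 20 seeded replicates of the full noisy
experiment, the fitted surface's maximizer typically lands within about
0.1 coded units of the noiseless-truth maximizer, with upper-tail draws
around 0.16 — count noise of 1--2 analytes per run propagated through the
Hessian is the limiting factor, not the optimizer.

## Numerical choices

* Least squares by QR with rank tolerance $10^{-10}$; rank deficiency is
  an error, not a silent pivot.
* Hessian eigenvalue zero-tolerance $10^{-8}$ relative; cube-optimization
  tie tolerance $10^{-10}$ relative.
* p-values straight from the F distribution's upper tail; printed as
  `<0.0001` below $10^{-4}$.
* Problem sizes in the tests: single 17-run designs throughout; 20 seeds
  for parameter recovery; 1000 replicates for the decision-limit
  calibration check (chosen so its Monte-Carlo standard error, ~0.005
  $\mu$g/kg, is well below the 0.05 band, which also accommodates the
  $c_4(18) \approx 0.985$ small-sample bias of the sample SD); 300 seeds
  for the matrix-effect centering check.

## A worked pass

```{r example, eval = FALSE}
des  <- bbd_design(c("A", "B", "C"))
surf <- sorbent_surface_example()          # bundled reference equation
y    <- construct_consistent_response(surf, 11.3, 2.8, des, seed = 1)
fit  <- rsm_fit(des, y)
summary(fit)                                # ANOVA + adequacy
optimize_surface(fit)                       # interior maximum, count 42

truth <- synthetic_truth(seed = 1)          # 43-analyte synthetic panel
qa    <- simulate_quant_assets(truth)
validation_summary(qa$replicates_02vl, qa$curves)
```

## Known limitations

* Only the three-factor Box-Behnken geometry is generated; central
  composite and larger designs are out of scope, as are blocking and run
  randomization.
* The ANOVA offers Type-III partial SS only; no stepwise selection,
  transformation, or weighted fits.
* Optimization is single-response; multi-response desirability and
  confidence regions around the optimum are not provided.
* Chromatographic signal processing (peak integration, S/N measurement)
  is upstream of this package: S/N ratios enter as numbers.
* The actual sorbent masses behind a published coded optimum cannot be
  recovered unless the factor ranges are supplied; results are flagged as
  coded-only in that case.
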