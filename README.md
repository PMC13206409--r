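# fmodal — functional L1-modal regression

`fmodal` predicts a scalar response from a **functional covariate** — a
curve observed on a common grid, such as a spectrum, a concentration
profile, or a sensor trace — using the **conditional mode** as the point
predictor. The mode is the natural target when the conditional law is
asymmetric or heavy-tailed and the mean or median would be misleading, and
it is the predictor of choice when the training responses may contain gross
errors.

The package is aimed at statisticians and analysts working with
scalar-on-function regression (chemometrics, environmental monitoring,
biomedical signals) who need a robust, fully data-driven kernel predictor
with honest bandwidth selection.

## The estimator

Instead of maximizing a kernel density estimate, the mode is located
through the conditional quantile function. Writing $\alpha(t \mid U)$ for
the conditional $t$-quantile of $V$ given the curve $U$, the quantile
density satisfies $\alpha'(t \mid U) = 1 / f(\alpha(t \mid U) \mid U)$, so

$$\widehat{LM}(U) = \hat\alpha(\hat t^* \mid U), \qquad
  \hat t^* = \arg\min_{t \in [a_U, b_U]} \hat\alpha'(t \mid U),$$

where $\hat\alpha(t \mid U) = \arg\min_s \sum_i W\!\big(Sd(U, U_i)/d\big)\,
\varrho_t(V_i - s)$ is the kernel-weighted check-loss quantile
($\varrho_t(r) = (2t-1)r + |r|$), $Sd$ a semi-metric between curves
(functional-PCA scores by default), $W$ a quadratic kernel, and
$\hat\alpha'$ a symmetric difference quotient. The weighted quantile is
computed in closed form (sorted responses, cumulative weights), which makes
$\hat\alpha$ exactly monotone in $t$ and the whole predictor fast enough
for leave-one-curve-out cross-validation at hundreds of curves.

Bandwidths are chosen by leave-one-curve-out CV over local ($k$-nearest
-neighbour radii) or global (pairwise-distance quantile) candidate grids,
under squared-error (LSCV) or absolute-error (QUCV) loss. Comparison
estimators — the kernel L1-median and the classical density-based kernel
mode — and a two-regime heteroscedastic curve simulator with SNR
calibration and a contamination harness round out the toolkit.

## Worked example

```r
library(fmodal)

# two-regime benchmark data: 400 curves on 100 grid points, SNR = 10%
cfg <- simulation_config(n1 = 200, n2 = 200, snr = 0.1, seed = 42)
fs  <- simulate_heteroscedastic(cfg)
fs
#> <functional_sample> 400 curves on 100 grid points [0, 1], with responses

# PCA semi-metric (3 components) and QUCV-local bandwidth selection
sm <- semimetric_pca(fs, p = 3)
cv <- loocv_select(fs, sm, predictor = "LM", scope = "local", loss_kind = "L1")
cv
#> <cv_result> local scope, L1 loss: selected 25 from 6 candidates
cv$criterion
#> [1] 0.1455783 0.1481550 0.1289560 0.1215870 0.1200296 0.1208557

# modal prediction at a curve, using its own 25-NN radius as bandwidth
new_curve <- fs$curves[7, ]
bw  <- local_bandwidth_grid(cross_distances(fs, sm, new_curve), cv$selected)
fit <- predict_mode_l1(fs, new_curve, bandwidth = bw, sm = sm)
fit
#> <modal_fit> mode 1.05583 at t* = 0.46 (min derivative 0.0216243, n_eff 25)
regression_operator(new_curve, fs$grid)   # the true conditional mode
#> [1] 1.113144
```

The CV criterion (mean absolute leave-one-out error per neighbour count
`k = 5, 10, ..., 30`) bottoms out at `k = 25`. The modal fit reports the
minimizing order `t* = 0.46` — near 0.5, as expected under symmetric
errors — and the predicted mode `1.056`, close to the true conditional
mode `r(U) = 1.113`.

The experiment drivers `run_selector_table()`, `run_mse_surface()` and
`run_contamination()` reproduce the full benchmark designs (selector
comparison table, bandwidth-by-SNR error surface, contamination
robustness) and write tidy CSV reports; `inst/cli/fmodal.R` exposes them,
plus simulation and fitting, as shell subcommands.

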