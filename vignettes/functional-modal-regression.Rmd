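---
title: "Functional L1-modal regression: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional L1-modal regression: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmodal)
```

## The model

We observe pairs $(U_i, V_i)$, $i = 1, \dots, n$, where $U_i$ is a curve
discretized on a common grid of $[0, 1]$ and $V_i$ a scalar response. The
goal is a robust point prediction of $V$ at a new curve $U$: the
*conditional mode*, the maximizer of the conditional density $f(\cdot \mid
U)$.

Rather than estimating that density directly, the package goes through the
conditional quantile function $\alpha(t \mid U)$. When the conditional
distribution function is strictly increasing with a continuous positive
density, the quantile function is differentiable in the order $t$ with

$$\alpha'(t \mid U) = \frac{1}{f(\alpha(t \mid U) \mid U)},$$

the *quantile density*. Its minimizer over $t$ sits exactly where the
conditional density peaks, so

$$\mathrm{mode}(U) = \alpha(t^* \mid U), \qquad
  t^* = \arg\min_{t \in [a_U, b_U]} \alpha'(t \mid U).$$

Estimating quantiles instead of densities is what buys robustness: the
quantile estimator solves a weighted check-loss (pinball) minimization, an
L1-type criterion whose solution is insensitive to the magnitude of extreme
responses.

## The estimator

Distances between curves are measured by a semi-metric $Sd$: either the
quadrature $L^2$ distance or, by default in the experiments, the
functional-PCA projection semi-metric — the Euclidean distance between the
first $p$ principal-component scores of the two curves, with the eigenbasis
estimated from the sample under the trapezoid inner product. Kernel weights
$w_i = W(Sd(U, U_i)/d)$ with a quadratic kernel $W(u) = (1 - u^2)_+$ then
localize the sample around the target curve, and

$$\hat\alpha(t \mid U)
  = \arg\min_s \sum_i w_i \,\varrho_t(V_i - s), \qquad
  \varrho_t(r) = (2t - 1) r + |r|,$$

is computed in closed form: sort the responses, accumulate normalized
weights, and return the smallest response whose cumulative weight reaches
$t$. This convention is always a minimizer of the weighted check loss,
resolves ties toward the smallest value, and makes $\hat\alpha$ *exactly*
nondecreasing in $t$ — so the difference-quotient derivative

$$\hat\alpha'(t \mid U)
  = \frac{\hat\alpha(t + \delta \mid U) - \hat\alpha(t - \delta \mid U)}
         {2\delta}$$

is exactly nonnegative. The modal fit minimizes $\hat\alpha'$ over an order
grid (ties toward the smallest order) and reads the mode off the quantile
curve.

Two comparison predictors are included: the kernel L1-median
$\widehat{ME}(U) = \hat\alpha(0.5 \mid U)$ (identical minimization with the
absolute loss), and the classical density-based kernel mode
$\widehat{MO}(U)$, the maximizer over a response grid of
$\sum_i w_i W(|V_i - v| / d_v)$.

## Tunable parameters

* **Bandwidth $d$** (unitless, on the semi-metric's scale) — the
  bias–variance dial. Selected by leave-one-curve-out cross-validation
  (below); no fixed default.
* **Order interval $[a_U, b_U]$** — default $(0.1, 0.9)$. The model never
  pins this down numerically; staying away from 0 and 1 keeps
  $t \pm \delta$ inside $(0,1)$ and avoids extreme-quantile instability.
* **Order grid** — default 81 equally spaced orders; the argmin tie-break
  is the smallest order.
* **Difference-quotient step $\delta$** — default 0.05. The theory reuses
  one smoothing symbol for both the kernel bandwidth and this step; we
  deliberately decouple them. Coupling would be an arbitrary special case,
  and the CV selectors tune only the kernel bandwidth. A wider $\delta$
  (0.1–0.15) trades a small bias for a visibly more stable argmin of the
  flat quantile density near its minimum — the validation suite uses 0.1
  for its distributional checks.
* **PCA truncation $p$** — default 3 in the experiments, matching the
  benchmark's reported choice.
* **Kernel support `u_max`** — default 1 with $W(u) = 1 - u^2$. The
  asymptotic theory posits support $(0, 1/2)$, but only the ratio
  distance/bandwidth enters the weights, so a support-$(0,1/2)$ kernel is
  the `u_max = 1` kernel at half the bandwidth; keeping `u_max = 1` keeps
  bandwidth grids interpretable as distances.
* **$\widehat{MO}$'s response bandwidth $d_v$** — defaults to Silverman's
  rule on the responses. Sharing one bandwidth across the curve metric and
  the response scale would be dimensionally arbitrary, so the two are
  independent parameters; the mode is searched on an explicit 201-point
  response grid (reproducible, tie-breakable) rather than by numerical
  ascent.

## Bandwidth selection

Candidates come in two scopes. The **local** grid attaches to each target
point the radii at which its ball contains exactly $k$ curves
($k \in \{5, 10, 15, 20, 25, 30\}$ by default, each radius inflated by
$10^{-9}$ so the $k$-th neighbour keeps positive weight). The **global**
grid is shared by all targets: empirical quantiles (orders
$\{0.02, 0.05, 0.1, 0.15, 0.2, 0.3, 0.5\}$) of all pairwise distances.
These defaults span sparse-to-oversmoothed regimes at a few hundred curves;
the benchmark publication states no grids.

The selector computes, per candidate, leave-one-curve-out predictions
$\hat V_i$ and the criterion $\mathrm{CV}(d) = \sum_i L(V_i - \hat V_i)$
with $L$ squared error (**LSCV**) or absolute error (**QUCV**). The QUCV
loss is never written out in the source material beyond "$L_p$"; we take
$p = 1$, consistent with the estimator's L1 theme (the only other natural
reading, a check loss, would need an order parameter that is never given).
For the local scope the neighbour count $k$ is what the criterion selects —
a per-point choice of $k$ is not identified by the single summed criterion
— and each evaluation point then uses its own $k$-NN radius. Candidates
with no valid prediction at any point get an infinite criterion; ties break
toward the smallest candidate. Criteria are reported as means over valid
points so that candidates with different validity counts remain comparable
(sum and mean share their argmin when the counts are equal; both are
stored).

The reported cross-validated error of the benchmark,
$MSE_{CV} = \frac{1}{n}\sum_i (V_i - \widetilde{LM}_{CV}(U_i))^2$, is
computed with the **full-sample** estimator refit at the selected bandwidth
and evaluated at the observed curves, per variability regime. Had it been
computed from the same leave-one-out predictions used for selection, the
LSCV rule would minimize it by construction and any comparison between
selectors would be vacuous; the refit reading is the only one under which
the benchmark's selector comparison is well-posed. The leave-one-out error
at the selected candidate is stored alongside as a diagnostic.

## The synthetic-data generator

`simulate_heteroscedastic()` draws two regimes of curves

$$U_i(t) = a_i \cos^4(b_i - t) + b_i + c\,\eta_{i,t},$$

with $a_i \sim N(-5, 0.5)$, $b_i \sim N(0, 2)$ (variances), and pointwise
curve noise $\eta_{i,t}$ of variance $0.05$ (regime S1, low variability)
or $1$ (S2, high variability), independent across curves and grid points —
the noise carries the subscripts $i$ and $t$, so independence across the
grid is the stated structure. Responses follow
$V_i = r(U_i) + \sigma_{k,\varepsilon}\varepsilon_i$ with standard normal
errors and $r(U) = 3\int_0^1 (1 + |U(t)|)^{-1}\,dt$; the regime noise scale
is calibrated so that $\sigma_{k,\varepsilon}^2$ equals a prescribed
signal-to-noise ratio times the empirical variance (population divisor, as
printed in the benchmark's definition) of $r$ over the regime. Under normal
errors the true conditional mode is exactly $r(U_i)$, which is what makes
the generator a parameter-recovery test bed.

Two under-specified constants are settled once: the cosine term is read as
a fourth **power** (`curve_form = "power"`; the frequency-4 reading
`cos(4(b_i - t))` is one flag away, and the validation suite checks the
benchmark bounds under both), and the curve-noise multiplier is $c = 1$, so
the printed $\eta$ variances directly drive the two variability regimes.
Within a replicate of the experiment drivers the curve sample and the
normal error draws are shared across SNR levels — $\sigma$ rescales one
error realization — which removes Monte-Carlo noise from cross-SNR
comparisons.

What the generator does *not* emulate: smooth (correlated-in-$t$) curve
noise, irregular or per-curve grids, non-Gaussian or asymmetric response
errors, and real spectral data such as NIR curves. Passing tests on this
generator therefore demonstrate correct mechanics and the expected
statistical orderings under a favorable, fully specified model — not
performance on real functional data.

## Numerical choices and degenerate inputs

* Quadrature is the trapezoid rule on the stored grid (exact for piecewise
  linear curves; weights sum to 1 on any grid spanning $[0,1]$).
* The PCA eigenproblem is symmetrized with $D = \mathrm{diag}(\sqrt{q})$
  so a standard symmetric `eigen()` applies; eigenfunctions are stored on
  the grid, orthonormal under the quadrature inner product to $10^{-8}$.
  A numerically zero covariance raises a degenerate-basis error.
* If every distance to a target exceeds the kernel support, estimators
  raise an `fmodal_empty_neighborhood` condition carrying the bandwidth —
  never a silent 0/0. In cross-validation such points are dropped from the
  criterion (and counted); a candidate with no valid points is excluded
  with an infinite criterion.
* The weighted-quantile convention "smallest value whose cumulative
  normalized weight reaches $t$" is exact; no interpolation is performed,
  so all quantile-based predictors are equivariant under increasing affine
  maps of the responses.
* Near-zero derivative denominators (a conditional density close to zero
  on the search range) are reported through the stored derivative values,
  not enforced against: the theory's positivity assumption has no
  practical check.

## Problem sizes in the validation suite

The acceptance-style checks run the full benchmark design: $n = 400$
curves on 100 grid points, five SNR levels, both scopes and both
selectors, 20 replicates (about a minute); the quantile-density and
sample-doubling checks use $n = 800$; the contamination harness uses
$n = 200$ with a 150/50 stratified split, levels $0$ to $0.5$, and 20
replicates. Unit tests run the same operations on samples of 3–30 curves
against brute-force oracles.

## Known limitations

* The modal fit minimizes over a finite order grid; its resolution (and
  the interval $[a_U, b_U]$) bounds how precisely $t^*$ is located.
* With contamination at or above half the neighbourhood mass, any median-
  or mode-type predictor can jump to the contaminated cluster; robustness
  comparisons are about the *range* of degradation, not immunity.
* The local-scope selection shares one $k$ across points; fully pointwise
  selection would require a pointwise criterion the summed CV rule does
  not provide.
* Semi-metric distances of the PCA kind can be zero for distinct curves;
  only symmetry, nonnegativity and self-distance zero are guaranteed.
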