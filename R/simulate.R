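#' Configuration of the two-regime heteroscedastic curve simulator
#'
#' The simulator draws curves
#' \deqn{U_i(t) = a_i \cos^4(b_i - t) + b_i + c\,\eta_{i,t}, \quad t \in [0,1],}
#' with \eqn{a_i \sim N(-5, 0.5)}, \eqn{b_i \sim N(0, 2)} (variances), and
#' grid-pointwise noise \eqn{\eta_{i,t}} whose standard deviation is
#' \eqn{\sqrt{0.05}} for the first `n1` curves (low-variability regime S1)
#' and 1 for the remaining `n2` (high-variability regime S2). Responses
#' follow \eqn{V_i = r(U_i) + \sigma_{k,\varepsilon} \varepsilon_i} with
#' standard normal errors and a regime-specific noise scale calibrated to a
#' signal-to-noise ratio (see [calibrate_noise()]); the regression operator
#' is \eqn{r(U) = 3\int_0^1 (1 + |U(t)|)^{-1} dt}. Under normal errors the
#' true conditional mode of \eqn{V} given \eqn{U = U_i} is \eqn{r(U_i)}.
#'
#' `curve_form` switches between reading the cosine term as a fourth power
#' (`"power"`, the default, \eqn{a_i \cos^4(b_i - t)}) and as a frequency-4
#' oscillation (`"frequency"`, \eqn{a_i \cos(4 (b_i - t))}).
#'
#' @param n1,n2 regime sizes (defaults 200 and 200).
#' @param snr signal-to-noise ratio used to calibrate the response noise
#'   (default 0.1).
#' @param grid_size number of equally spaced grid points on \eqn{[0,1]}
#'   (default 100).
#' @param a_mean,a_sd,b_mean,b_sd distribution of the curve coefficients.
#' @param eta_sd1,eta_sd2 pointwise curve-noise standard deviations per
#'   regime.
#' @param c curve-noise multiplier (default 1).
#' @param curve_form `"power"` or `"frequency"`.
#' @param seed integer seed; every generator call is deterministic given it.
#' @return a list of class `"simulation_config"`.
#' @export
simulation_config <- function(n1 = 200L, n2 = 200L, snr = 0.1,
                              grid_size = 100L,
                              a_mean = -5, a_sd = sqrt(0.5),
                              b_mean = 0, b_sd = sqrt(2),
                              eta_sd1 = sqrt(0.05), eta_sd2 = 1,
                              c = 1,
                              curve_form = c("power", "frequency"),
                              seed = 1L) {
  curve_form <- match.arg(curve_form)
  if (n1 < 1L || n2 < 1L) stop_invalid("regime sizes must be at least 1")
  if (snr < 0) stop_invalid("snr must be nonnegative")
  if (any(c(a_sd, b_sd, eta_sd1, eta_sd2) < 0))
    stop_invalid("standard deviations must be nonnegative")
  structure(list(n1 = as.integer(n1), n2 = as.integer(n2), snr = snr,
                 grid_size = as.integer(grid_size),
                 a_mean = a_mean, a_sd = a_sd, b_mean = b_mean, b_sd = b_sd,
                 eta_sd1 = eta_sd1, eta_sd2 = eta_sd2, c = c,
                 curve_form = curve_form, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Generate the functional covariates of the simulation model
#'
#' Draws `n1 + n2` curves on `grid_size` equally spaced points of
#' \eqn{[0, 1]} (see [simulation_config()] for the model). Deterministic
#' given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return a [functional_sample()] without responses, with `regime` labels
#'   (1 for S1, 2 for S2).
#' @export
generate_curves <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n1 + config$n2
  m <- config$grid_size
  tg <- seq(0, 1, length.out = m)
  a <- stats::rnorm(n, config$a_mean, config$a_sd)
  b <- stats::rnorm(n, config$b_mean, config$b_sd)
  eta <- rbind(
    matrix(stats::rnorm(config$n1 * m, 0, config$eta_sd1), config$n1, m),
    matrix(stats::rnorm(config$n2 * m, 0, config$eta_sd2), config$n2, m))
  phase <- outer(b, tg, "-")
  smooth <- a * switch(config$curve_form,
                       power = cos(phase)^4,
                       frequency = cos(4 * phase))
  curves <- smooth + b + config$c * eta
  functional_sample(tg, curves,
                    regime = rep(1:2, c(config$n1, config$n2)))
}

#' Regression operator r(U)
#'
#' \eqn{r(U) = 3 \int_0^1 (1 + |U(t)|)^{-1} dt}, evaluated by trapezoid
#' quadrature on the curve's grid. The integrand is bounded in \eqn{(0, 3]},
#' so `r` always lies in that interval.
#'
#' @param curve numeric vector (one curve) or matrix (one curve per row).
#' @param grid the evaluation grid, spanning \eqn{[0, 1]}.
#' @return numeric vector of operator values, one per curve.
#' @export
regression_operator <- function(curve, grid) {
  if (is.vector(curve)) curve <- matrix(curve, nrow = 1)
  if (ncol(curve) != length(grid))
    stop_invalid("curve and grid lengths disagree")
  qw <- trapezoid_weights(grid)
  as.vector((3 / (1 + abs(curve))) %*% qw)
}

#' Calibrate the response-noise scale from a signal-to-noise ratio
#'
#' The signal-to-noise ratio of a regime is defined as the response-noise
#' variance divided by the empirical variance (population divisor) of the
#' regression-operator values over that regime:
#' \eqn{SNR_k = \sigma_{k,\varepsilon}^2 / \frac{1}{n_k}\sum_{i \in S_k}
#' (r(U_i) - \bar r)^2}. Given the target SNR this returns
#' \eqn{\sigma_{k,\varepsilon} = \sqrt{SNR \cdot \widehat{Var}(r)}}.
#'
#' @param r_values the regression-operator values over one regime (length
#'   at least 2).
#' @param snr nonnegative signal-to-noise ratio.
#' @return the noise standard deviation \eqn{\sigma_{k,\varepsilon}}.
#' @export
calibrate_noise <- function(r_values, snr) {
  if (length(r_values) < 2L) stop_invalid("need at least two operator values")
  if (snr < 0) stop_invalid("snr must be nonnegative")
  v <- mean((r_values - mean(r_values))^2)
  if (v == 0) stop_degenerate("regression operator is constant over the regime")
  sqrt(snr * v)
}

#' Attach simulated responses to generated curves
#'
#' Computes \eqn{r(U_i)}, calibrates the per-regime noise scale to
#' `config$snr`, and draws \eqn{V_i = r(U_i) + \sigma_{k,\varepsilon}
#' \varepsilon_i} with i.i.d. standard normal \eqn{\varepsilon_i}.
#' The error draw is seeded independently of the curve draw (offset seed),
#' so regenerating responses at a different SNR rescales the same error
#' realization.
#'
#' @param sample a [functional_sample()] with `regime` labels (from
#'   [generate_curves()]).
#' @param config the [simulation_config()].
#' @return the sample with `responses` filled in.
#' @export
generate_responses <- function(sample, config) {
  stopifnot(inherits(sample, "functional_sample"),
            inherits(config, "simulation_config"))
  if (is.null(sample$regime)) stop_invalid("sample has no regime labels")
  r <- regression_operator(sample$curves, sample$grid)
  n <- length(r)
  sigma <- numeric(n)
  for (k in unique(sample$regime)) {
    idx <- sample$regime == k
    sigma[idx] <- if (config$snr == 0) 0 else
      calibrate_noise(r[idx], config$snr)
  }
  set.seed(config$seed + 1000003L)
  eps <- stats::rnorm(n)
  functional_sample(sample$grid, sample$curves,
                    responses = r + sigma * eps,
                    regime = sample$regime)
}

#' @rdname generate_responses
#' @description `simulate_heteroscedastic()` runs both steps:
#'   curves then responses.
#' @export
simulate_heteroscedastic <- function(config) {
  generate_responses(generate_curves(config), config)
}

#' Contamination of responses by a gross-error factor
#'
#' `contaminate()` multiplies exactly `floor(proportion * n)` uniformly
#' chosen entries of a response vector by `factor` (default 10), leaving the
#' rest untouched; the choice of entries is deterministic given the spec's
#' seed.
#'
#' @param proportion contamination level in \eqn{[0, 1]}.
#' @param factor multiplier applied to contaminated entries.
#' @param seed integer seed for the choice of entries.
#' @return `contamination_spec()` returns a spec list; `contaminate()` the
#'   modified response vector.
#' @export
contamination_spec <- function(proportion, factor = 10, seed = 1L) {
  if (proportion < 0 || proportion > 1)
    stop_invalid("proportion must lie in [0, 1]")
  structure(list(proportion = proportion, factor = factor,
                 seed = as.integer(seed)),
            class = "contamination_spec")
}

#' @rdname contamination_spec
#' @param responses numeric response vector.
#' @param spec a `contamination_spec`.
#' @export
contaminate <- function(responses, spec) {
  stopifnot(inherits(spec, "contamination_spec"))
  n <- length(responses)
  m <- floor(spec$proportion * n)
  if (m == 0L) return(responses)
  set.seed(spec$seed)
  idx <- sample.int(n, m)
  responses[idx] <- responses[idx] * spec$factor
  responses
}

#' Split a functional sample into training and test sets
#'
#' Disjoint, exhaustive split; with `stratified = TRUE` the training set
#' contains an equal share of each regime (requires `n_train` and each
#' regime size to be divisible accordingly, e.g. 300 of 400 with two regimes
#' of 200 gives 150 + 150 train and 50 + 50 test).
#'
#' @param sample a [functional_sample()].
#' @param n_train training-set size (`< n`).
#' @param stratified stratify on `sample$regime`?
#' @param seed integer seed.
#' @return list with elements `train` and `test` (functional samples) and
#'   `train_idx`, `test_idx`.
#' @export
train_test_split <- function(sample, n_train, stratified = TRUE, seed = 1L) {
  n <- n_curves(sample)
  n_train <- as.integer(n_train)
  if (n_train < 1L || n_train >= n)
    stop_invalid("n_train must lie in [1, n - 1]")
  set.seed(seed)
  if (stratified) {
    if (is.null(sample$regime))
      stop_invalid("stratified split requires regime labels")
    strata <- split(seq_len(n), sample$regime)
    shares <- vapply(strata, function(s)
      n_train * length(s) / n, numeric(1))
    if (any(shares != round(shares)))
      stop_invalid("n_train is not divisible across the regimes")
    train_idx <- sort(unlist(mapply(function(s, k) sample(s, k),
                                    strata, as.integer(shares),
                                    SIMPLIFY = FALSE), use.names = FALSE))
  } else {
    train_idx <- sort(sample.int(n, n_train))
  }
  test_idx <- setdiff(seq_len(n), train_idx)
  subset_fs <- function(idx)
    functional_sample(sample$grid, sample$curves[idx, , drop = FALSE],
                      responses = sample$responses[idx],
                      regime = sample$regime[idx])
  list(train = subset_fs(train_idx), test = subset_fs(test_idx),
       train_idx = train_idx, test_idx = test_idx)
}
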