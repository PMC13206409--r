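#' Conditional mode from a quantile curve (L1-modal regression)
#'
#' The quantile-density identity \eqn{\alpha'(t \mid U) = 1 / f(\alpha(t \mid
#' U) \mid U)} says the derivative of the conditional quantile function is
#' smallest where the conditional density is largest, so the conditional mode
#' is \eqn{\alpha(t^* \mid U)} with \eqn{t^* = \arg\min_t \alpha'(t \mid U)}.
#' This function minimizes the estimated derivative over the order grid
#' (ties broken toward the smallest order) and reads the mode off the
#' quantile curve.
#'
#' @param qc a [quantile_curve()].
#' @return An object of class `"modal_fit"`: list with `t_star` (minimizing
#'   order), `mode` (\eqn{\hat\alpha(\hat t^* \mid U)}), `derivative_min`,
#'   `n_effective`.
#' @export
mode_from_quantile_curve <- function(qc) {
  stopifnot(inherits(qc, "quantile_curve"))
  i <- which.min(qc$derivatives)  # first minimum = smallest order
  structure(list(t_star = qc$orders[i], mode = qc$values[i],
                 derivative_min = qc$derivatives[i],
                 n_effective = qc$n_effective),
            class = "modal_fit")
}

#' @export
print.modal_fit <- function(x, ...) {
  cat(sprintf("<modal_fit> mode %.6g at t* = %.4g (min derivative %.6g, n_eff %d)\n",
              x$mode, x$t_star, x$derivative_min, x$n_effective))
  invisible(x)
}

#' The three kernel predictors: L1-mode, L1-median, density mode
#'
#' `predict_mode_l1()` is the package's main predictor: the conditional mode
#' estimated through the derivative of the check-loss conditional quantile
#' (see [mode_from_quantile_curve()]). `predict_median()` is the kernel
#' L1-median, i.e. the conditional quantile at order 0.5 — the same weighted
#' minimization with the absolute loss. `predict_mode_density()` is the
#' classical density-based kernel mode: the maximizer over a response grid of
#' the doubly-weighted sum \eqn{\sum_i W(Sd(U,U_i)/d_x)\, W(|V_i - v| /
#' d_v)}, with a symmetric quadratic response kernel.
#'
#' @inheritParams conditional_quantile
#' @param control a [modal_control()] with the order grid and derivative step.
#' @return `predict_mode_l1()` returns a `modal_fit`; the others a single
#'   number.
#' @examples
#' cfg <- simulation_config(n1 = 30, n2 = 30, seed = 1)
#' fs <- simulate_heteroscedastic(cfg)
#' sm <- semimetric_pca(fs, p = 3)
#' predict_mode_l1(fs, fs$curves[1, ], bandwidth = 1, sm = sm)
#' @export
predict_mode_l1 <- function(sample, target, bandwidth, sm,
                            kernel = fkernel(), control = modal_control()) {
  qc <- quantile_curve(sample, target, bandwidth, sm, kernel,
                       orders = control$orders, step = control$step)
  mode_from_quantile_curve(qc)
}

#' @rdname predict_mode_l1
#' @export
predict_median <- function(sample, target, bandwidth, sm,
                           kernel = fkernel()) {
  conditional_quantile(sample, target, orders = 0.5, bandwidth = bandwidth,
                       sm = sm, kernel = kernel)
}

#' @rdname predict_mode_l1
#' @param bandwidth_x bandwidth for the curve-distance kernel.
#' @param bandwidth_v bandwidth for the response kernel; default Silverman's
#'   rule-of-thumb ([stats::bw.nrd0()]) on the responses.
#' @param v_grid response grid the mode is searched over; default 201 equally
#'   spaced points spanning the response range. Ties break toward the
#'   smallest grid value.
#' @export
predict_mode_density <- function(sample, target, bandwidth_x,
                                 bandwidth_v = NULL, sm,
                                 kernel = fkernel(), v_grid = NULL) {
  if (is.null(sample$responses)) stop_invalid("sample has no responses")
  d <- as.vector(cross_distances(sample, sm, target))
  wp <- kernel_weights(d, bandwidth_x, kernel)
  if (wp$n_effective == 0L) stop_empty_neighborhood(bandwidth_x)
  if (is.null(bandwidth_v)) bandwidth_v <- stats::bw.nrd0(sample$responses)
  if (is.null(v_grid))
    v_grid <- seq(min(sample$responses), max(sample$responses),
                  length.out = 201L)
  mode_density_wv(sample$responses, wp$weights, bandwidth_v, v_grid)
}

# Core of the density-based mode: weighted kernel density on a grid, argmax.
mode_density_wv <- function(values, weights, bandwidth_v, v_grid) {
  if (bandwidth_v <= 0) stop_invalid("bandwidth_v must be positive")
  keep <- weights > 0
  values <- values[keep]; weights <- weights[keep]
  # density on the grid: sum_i w_i * (1 - u^2)_+ with u = |v_i - v| / h_v
  u <- abs(outer(values, v_grid, "-")) / bandwidth_v
  dens <- colSums(weights * (1 - u^2) * (u < 1))
  if (all(dens <= 0))
    stop_degenerate("all density values are zero on the response grid")
  v_grid[which.max(dens)]
}

#' Control parameters of the modal estimator
#'
#' Bundles the order grid and difference-quotient step used by the L1-modal
#' predictor.
#'
#' @param interval order interval \eqn{(a_U, b_U)}, default `c(0.1, 0.9)`.
#' @param n_orders grid size (default 81).
#' @param step derivative step \eqn{\delta} (default 0.05).
#' @return list with `orders`, `interval`, `step`.
#' @export
modal_control <- function(interval = c(0.1, 0.9), n_orders = 81L,
                          step = 0.05) {
  if (interval[1] - step <= 0 || interval[2] + step >= 1)
    stop_invalid("interval +/- step must stay inside (0, 1)")
  list(orders = seq(interval[1], interval[2], length.out = n_orders),
       interval = interval, step = step)
}

# Fast internal predictors operating on precomputed (values, weights);
# used by the cross-validation loops and experiment drivers.
mode_l1_wv <- function(values, weights, control) {
  keep <- weights > 0
  qc <- quantile_curve_wv(values[keep], weights[keep],
                          orders = control$orders, step = control$step)
  qc$values[which.min(qc$derivatives)]
}

median_wv <- function(values, weights) {
  keep <- weights > 0
  sw <- sorted_weighted(values[keep], weights[keep])
  quantile_lookup(sw, 0.5)
}

#' Write predictions as a two-column CSV (index, prediction)
#'
#' @param predictions numeric vector.
#' @param file output path.
#' @export
write_predictions <- function(predictions, file) {
  utils::write.csv(data.frame(index = seq_along(predictions),
                              prediction = predictions),
                   file, row.names = FALSE)
  invisible(predictions)
}
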