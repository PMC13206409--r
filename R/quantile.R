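#' Check (pinball) loss
#'
#' The asymmetric absolute loss \eqn{\varrho_t(r) = (2t - 1) r + |r|} whose
#' population minimizer is the order-`t` quantile. At `t = 0.5` it reduces to
#' the absolute loss \eqn{|r|}; for positive residuals the slope is \eqn{2t},
#' for negative residuals \eqn{-2(1 - t)}.
#'
#' @param order quantile order(s) in (0, 1); recycled against `residual`.
#' @param residual numeric residual(s).
#' @return nonnegative numeric vector.
#' @examples
#' check_loss(0.5, c(-2, 3))   # absolute loss
#' check_loss(0.25, 2)         # 2 * 0.25 * 2
#' @export
check_loss <- function(order, residual) {
  if (any(order <= 0 | order >= 1)) stop_invalid("order must lie in (0, 1)")
  (2 * order - 1) * residual + abs(residual)
}

#' Weighted quantile minimizing the check loss
#'
#' The exact minimizer of \eqn{\sum_i w_i \varrho_t(v_i - s)} over `s`,
#' computed in closed form: sort the values ascending, accumulate normalized
#' weights, and return the smallest value whose cumulative weight reaches the
#' order. That convention always is a minimizer of the weighted check loss,
#' returns the smallest one under ties, and makes the quantile exactly
#' nondecreasing in the order.
#'
#' @param values numeric vector.
#' @param weights nonnegative weights, same length; at least one positive.
#' @param orders quantile order(s) in (0, 1); may be a vector.
#' @return numeric vector, one quantile per order.
#' @examples
#' weighted_quantile(c(1, 2, 3), rep(1, 3), 0.5)  # 2
#' @export
weighted_quantile <- function(values, weights, orders) {
  if (length(values) != length(weights))
    stop_invalid("values and weights must have equal length")
  if (any(weights < 0) || any(!is.finite(weights)))
    stop_invalid("weights must be finite and nonnegative")
  if (any(orders <= 0 | orders >= 1)) stop_invalid("orders must lie in (0, 1)")
  keep <- weights > 0
  if (!any(keep)) stop_empty_neighborhood(NA_real_)
  sw <- sorted_weighted(values[keep], weights[keep])
  quantile_lookup(sw, orders)
}

# Sorted values + normalized cumulative weights; the shared fast path for
# every quantile-based estimator.
sorted_weighted <- function(values, weights) {
  o <- order(values)
  v <- values[o]
  cw <- cumsum(weights[o])
  list(v = v, cw = cw / cw[length(cw)])
}

# Smallest v whose cumulative normalized weight reaches each order.
quantile_lookup <- function(sw, orders) {
  idx <- findInterval(orders, sw$cw, left.open = TRUE) + 1L
  sw$v[pmin(idx, length(sw$v))]
}

#' Kernel-weighted conditional quantile at a target curve
#'
#' The functional Nadaraya–Watson-type check-loss estimator
#' \eqn{\hat\alpha(t \mid U) = \arg\min_s \sum_i W(Sd(U, U_i)/d)\,
#' \varrho_t(V_i - s)}: distances from the target to all sample curves are
#' turned into kernel weights, and the weighted quantile of the responses is
#' returned.
#'
#' @param sample a [functional_sample()] with responses.
#' @param target numeric vector, the curve \eqn{U} on the sample's grid.
#' @param orders quantile order(s) in (0, 1).
#' @param bandwidth positive kernel bandwidth.
#' @param sm a semi-metric (see [semimetric_pca()]).
#' @param kernel an [fkernel()].
#' @return numeric vector of conditional quantile estimates, one per order.
#' @export
conditional_quantile <- function(sample, target, orders, bandwidth,
                                 sm, kernel = fkernel()) {
  if (is.null(sample$responses)) stop_invalid("sample has no responses")
  d <- as.vector(cross_distances(sample, sm, target))
  wp <- kernel_weights(d, bandwidth, kernel)
  if (wp$n_effective == 0L) stop_empty_neighborhood(bandwidth)
  keep <- wp$weights > 0
  sw <- sorted_weighted(sample$responses[keep], wp$weights[keep])
  quantile_lookup(sw, orders)
}

#' Conditional quantile curve with difference-quotient derivative
#'
#' Evaluates the conditional quantile \eqn{\hat\alpha(t \mid U)} on a grid of
#' orders inside an interval \eqn{[a_U, b_U] \subset (0, 1)} and its
#' derivative by the symmetric difference quotient
#' \eqn{\hat\alpha'(t \mid U) = (\hat\alpha(t + \delta \mid U) -
#' \hat\alpha(t - \delta \mid U)) / (2\delta)}. The derivative is the
#' quantile-density estimate whose minimizer locates the conditional mode.
#'
#' @inheritParams conditional_quantile
#' @param orders strictly increasing order grid; default `n_orders` equally
#'   spaced points spanning `interval`.
#' @param interval the order interval \eqn{(a_U, b_U)}; default `c(0.1, 0.9)`.
#' @param n_orders number of grid orders (default 81).
#' @param step difference-quotient half-width \eqn{\delta} (default 0.05);
#'   `orders - step` and `orders + step` must stay inside (0, 1).
#' @return An object of class `"quantile_curve"`: list with `orders`,
#'   `values`, `derivatives`, `step`, `interval`, `n_effective`.
#' @export
quantile_curve <- function(sample, target, bandwidth, sm,
                           kernel = fkernel(), orders = NULL,
                           interval = c(0.1, 0.9), n_orders = 81L,
                           step = 0.05) {
  if (is.null(sample$responses)) stop_invalid("sample has no responses")
  d <- as.vector(cross_distances(sample, sm, target))
  wp <- kernel_weights(d, bandwidth, kernel)
  if (wp$n_effective == 0L) stop_empty_neighborhood(bandwidth)
  keep <- wp$weights > 0
  quantile_curve_wv(sample$responses[keep], wp$weights[keep],
                    orders = orders, interval = interval,
                    n_orders = n_orders, step = step,
                    n_effective = wp$n_effective)
}

# Core: quantile curve from (already positive) weights and values.
quantile_curve_wv <- function(values, weights, orders = NULL,
                              interval = c(0.1, 0.9), n_orders = 81L,
                              step = 0.05, n_effective = length(values)) {
  if (is.null(orders))
    orders <- seq(interval[1], interval[2], length.out = n_orders)
  orders <- as.numeric(orders)
  if (is.unsorted(orders, strictly = TRUE))
    stop_invalid("orders must be strictly increasing")
  if (!is.numeric(step) || length(step) != 1L || step <= 0)
    stop_invalid("step must be a positive number")
  if (orders[1] - step <= 0 || orders[length(orders)] + step >= 1)
    stop_invalid("orders +/- step must stay inside (0, 1)")
  G <- length(orders)
  sw <- sorted_weighted(values, weights)
  q <- quantile_lookup(sw, c(orders - step, orders, orders + step))
  structure(list(orders = orders,
                 values = q[(G + 1L):(2L * G)],
                 derivatives = (q[(2L * G + 1L):(3L * G)] - q[1:G]) /
                   (2 * step),
                 step = step,
                 interval = c(orders[1], orders[G]),
                 n_effective = n_effective),
            class = "quantile_curve")
}

#' @export
print.quantile_curve <- function(x, ...) {
  cat(sprintf(
    "<quantile_curve> %d orders in [%g, %g], step %g, n_effective %d\n",
    length(x$orders), x$interval[1], x$interval[2], x$step, x$n_effective))
  invisible(x)
}

#' Write a quantile curve to CSV (orders, values, derivatives)
#'
#' @param qc a [quantile_curve()].
#' @param file output path.
#' @export
write_quantile_curve <- function(qc, file) {
  utils::write.csv(data.frame(order = qc$orders, value = qc$values,
                              derivative = qc$derivatives),
                   file, row.names = FALSE)
  invisible(qc)
}
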