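#' Asymmetric smoothing kernels on distances
#'
#' Kernels used to weight sample curves by their semi-metric distance to a
#' target. Because semi-metric distances are nonnegative, the kernel lives on
#' `[0, u_max)`:
#'
#' * `"quadratic"`: \eqn{W(u) = 1 - (u / u_{max})^2} for \eqn{0 \le u <
#'   u_{max}}, 0 elsewhere;
#' * `"uniform"`: \eqn{W(u) = 1} on \eqn{[0, u_{max})}, 0 elsewhere.
#'
#' Only the ratio distance/bandwidth enters the weights, so the support bound
#' `u_max` and the bandwidth trade off against each other; a kernel supported
#' on `(0, 1/2)` is the `u_max = 1` kernel at half the bandwidth.
#'
#' @param shape `"quadratic"` (default) or `"uniform"`.
#' @param u_max positive upper support bound (default 1).
#' @return an object of class `"fkernel"`.
#' @examples
#' k <- fkernel()
#' kernel_eval(k, c(0, 0.5, 2))
#' @export
fkernel <- function(shape = c("quadratic", "uniform"), u_max = 1) {
  shape <- match.arg(shape)
  if (!is.numeric(u_max) || length(u_max) != 1L || !is.finite(u_max) ||
      u_max <= 0)
    stop_invalid("u_max must be a positive number")
  structure(list(shape = shape, u_max = u_max), class = "fkernel")
}

#' @rdname fkernel
#' @param kernel an `fkernel`.
#' @param u numeric vector of nonnegative evaluation points.
#' @export
kernel_eval <- function(kernel, u) {
  inside <- u >= 0 & u < kernel$u_max
  w <- numeric(length(u))
  w[inside] <- switch(kernel$shape,
                      quadratic = 1 - (u[inside] / kernel$u_max)^2,
                      uniform = 1)
  w
}

#' @export
print.fkernel <- function(x, ...) {
  cat(sprintf("<fkernel> %s on [0, %g)\n", x$shape, x$u_max))
  invisible(x)
}

#' Kernel weights of a sample relative to a target
#'
#' Computes \eqn{w_i = W(Sd(U, U_i) / d)} for a vector of distances to a
#' target curve and a bandwidth `d`. `n_effective` counts the strictly
#' positive weights; downstream estimators raise an empty-neighborhood error
#' when it is zero rather than dividing by a zero weight total.
#'
#' @param distances numeric vector of nonnegative distances to the target.
#' @param bandwidth positive smoothing parameter `d`.
#' @param kernel an [fkernel()] (default quadratic, `u_max = 1`).
#' @return An object of class `"weight_profile"`: list with `weights`,
#'   `bandwidth`, `n_effective`.
#' @export
kernel_weights <- function(distances, bandwidth, kernel = fkernel()) {
  if (!is.numeric(bandwidth) || length(bandwidth) != 1L ||
      !is.finite(bandwidth) || bandwidth <= 0)
    stop_invalid("bandwidth must be a positive number")
  w <- kernel_eval(kernel, distances / bandwidth)
  structure(list(weights = w, bandwidth = bandwidth,
                 n_effective = sum(w > 0)),
            class = "weight_profile")
}

#' @export
print.weight_profile <- function(x, ...) {
  cat(sprintf("<weight_profile> bandwidth %g, %d of %d weights positive\n",
              x$bandwidth, x$n_effective, length(x$weights)))
  invisible(x)
}
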