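#' Functional sample: curves on a common grid with optional scalar responses
#'
#' The basic data container of the package: `n` curves \eqn{U_i} discretized
#' on a shared, strictly increasing grid of `m` points (conventionally on
#' \eqn{[0, 1]}), together with an optional length-`n` scalar response vector
#' \eqn{V_i}. All estimators in the package consume this container.
#'
#' @param grid strictly increasing numeric vector of length `m`, the common
#'   evaluation points of the curves.
#' @param curves numeric `n x m` matrix; row `i` is the curve \eqn{U_i}
#'   evaluated on `grid`.
#' @param responses optional numeric vector of length `n`, the scalar
#'   responses \eqn{V_i}.
#' @param regime optional integer vector of length `n` labelling a stratum
#'   (e.g. the variance regime of the simulator); used by
#'   [train_test_split()] for stratification.
#'
#' @return An object of class `"functional_sample"`: a list with elements
#'   `grid`, `curves`, `responses`, `regime`.
#' @examples
#' fs <- functional_sample(seq(0, 1, length.out = 5),
#'                         matrix(rnorm(15), nrow = 3))
#' n_curves(fs)
#' @export
functional_sample <- function(grid, curves, responses = NULL, regime = NULL) {
  grid <- as.numeric(grid)
  if (is.vector(curves)) curves <- matrix(curves, nrow = 1)
  curves <- as.matrix(curves)
  storage.mode(curves) <- "double"
  if (length(grid) < 2L)
    stop_invalid("grid must contain at least two points")
  if (any(!is.finite(grid)) || any(diff(grid) <= 0))
    stop_invalid("grid must be finite and strictly increasing")
  if (ncol(curves) != length(grid))
    stop_invalid("curves must have one column per grid point")
  if (any(!is.finite(curves)))
    stop_invalid("curve values must all be finite")
  if (!is.null(responses)) {
    responses <- as.numeric(responses)
    if (length(responses) != nrow(curves))
      stop_invalid("responses must have one value per curve")
    if (any(!is.finite(responses)))
      stop_invalid("responses must all be finite")
  }
  if (!is.null(regime)) {
    regime <- as.integer(regime)
    if (length(regime) != nrow(curves))
      stop_invalid("regime labels must have one value per curve")
  }
  structure(list(grid = grid, curves = curves,
                 responses = responses, regime = regime),
            class = "functional_sample")
}

#' @rdname functional_sample
#' @param x a `functional_sample`.
#' @export
n_curves <- function(x) nrow(x$curves)

#' @export
print.functional_sample <- function(x, ...) {
  cat(sprintf("<functional_sample> %d curves on %d grid points [%g, %g]%s\n",
              nrow(x$curves), length(x$grid),
              min(x$grid), max(x$grid),
              if (is.null(x$responses)) "" else ", with responses"))
  invisible(x)
}

#' Trapezoid quadrature weights for a grid
#'
#' Weights `w` such that `sum(w * f)` is the trapezoid-rule approximation of
#' \eqn{\int f} over the grid's span. Exact for piecewise-linear integrands;
#' on any grid spanning \eqn{[0, 1]} the weights sum to 1.
#'
#' @param grid strictly increasing numeric vector.
#' @return numeric vector of nonnegative weights, same length as `grid`.
#' @export
trapezoid_weights <- function(grid) {
  m <- length(grid)
  if (m < 2L) stop_invalid("grid must contain at least two points")
  h <- diff(grid)
  c(h[1], h[-1] + h[-(m - 1)], h[m - 1]) / 2
}

# -- CSV interface -----------------------------------------------------------
# Wide curve format: first row = grid values, each subsequent row = one curve.
# Responses: single column, aligned with curve rows. Numbers are written with
# 17 significant digits so a write/read cycle reproduces the doubles exactly.

#' Read and write functional samples as CSV
#'
#' Curves are stored wide: the first CSV row holds the grid values and each
#' subsequent row one curve. Responses are a separate single-column CSV
#' aligned with the curve rows. Values round-trip bit-exactly.
#'
#' @param curves_file path of the curve CSV.
#' @param responses_file optional path of the response CSV.
#' @return `read_functional_sample()` returns a [functional_sample()];
#'   `write_functional_sample()` returns its input, invisibly.
#' @export
read_functional_sample <- function(curves_file, responses_file = NULL) {
  mat <- as.matrix(utils::read.csv(curves_file, header = FALSE,
                                   colClasses = "numeric"))
  dimnames(mat) <- NULL
  responses <- NULL
  if (!is.null(responses_file))
    responses <- utils::read.csv(responses_file, header = FALSE,
                                 colClasses = "numeric")[[1]]
  functional_sample(grid = mat[1, ], curves = mat[-1, , drop = FALSE],
                    responses = responses)
}

#' @rdname read_functional_sample
#' @param sample a `functional_sample`.
#' @export
write_functional_sample <- function(sample, curves_file,
                                    responses_file = NULL) {
  fmt <- function(x) sprintf("%.17g", x)
  lines <- c(paste(fmt(sample$grid), collapse = ","),
             apply(sample$curves, 1, function(r) paste(fmt(r), collapse = ",")))
  writeLines(lines, curves_file)
  if (!is.null(responses_file)) {
    if (is.null(sample$responses))
      stop_invalid("sample has no responses to write")
    writeLines(fmt(sample$responses), responses_file)
  }
  invisible(sample)
}

# -- error conditions --------------------------------------------------------

stop_invalid <- function(msg) {
  stop(errorCondition(msg, class = c("fmodal_invalid_argument", "fmodal_error")))
}

stop_empty_neighborhood <- function(bandwidth) {
  stop(errorCondition(
    sprintf("no sample curve within kernel support at bandwidth %g", bandwidth),
    bandwidth = bandwidth,
    class = c("fmodal_empty_neighborhood", "fmodal_error")))
}

stop_degenerate <- function(msg) {
  stop(errorCondition(msg, class = c("fmodal_degenerate", "fmodal_error")))
}
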