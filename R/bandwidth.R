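#' Candidate bandwidth grids
#'
#' Two ways of building the candidate set the cross-validation selectors
#' search over:
#'
#' * `local_bandwidth_grid(distances, k_values)` — for one target point, the
#'   radius at which the ball centered at the target contains exactly `k`
#'   sample curves: the `k`-th order statistic of the distances, inflated by
#'   `1e-9` so the `k`-th point has strictly positive kernel weight.
#' * `global_bandwidth_grid(pairwise, q_values)` — empirical quantiles of
#'   order `q` of all strictly-upper-triangle pairwise distances, shared by
#'   every target; zero candidates are dropped.
#'
#' The grid minimum and maximum play the role of the admissible bandwidth
#' range within which data-driven selection is theoretically supported.
#'
#' @param distances nonnegative distances from the target to the sample
#'   curves.
#' @param k_values positive integers, numbers of neighbours (each `<=
#'   length(distances)`).
#' @return numeric vector of positive candidates, ascending.
#' @export
local_bandwidth_grid <- function(distances, k_values) {
  k_values <- as.integer(k_values)
  if (any(is.na(k_values)) || any(k_values < 1L) ||
      any(k_values > length(distances)))
    stop_invalid("k_values must be integers in [1, length(distances)]")
  sort(sort(distances)[k_values]) + 1e-9
}

#' @rdname local_bandwidth_grid
#' @param pairwise symmetric `n x n` distance matrix (see
#'   [pairwise_distances()]).
#' @param q_values quantile orders in (0, 1].
#' @export
global_bandwidth_grid <- function(pairwise, q_values) {
  if (nrow(pairwise) < 2L) stop_invalid("need at least two curves")
  if (any(q_values <= 0 | q_values > 1))
    stop_invalid("q_values must lie in (0, 1]")
  d <- pairwise[upper.tri(pairwise)]
  if (all(d == 0)) stop_degenerate("all pairwise distances are zero")
  cand <- unname(stats::quantile(d, sort(q_values)))
  cand <- cand[cand > 0]
  if (length(cand) == 0L) stop_degenerate("all candidate bandwidths are zero")
  cand
}

#' Default candidate parameters
#'
#' The package-wide defaults: `k` spanning sparse to oversmoothed
#' neighbourhoods at a few hundred curves, and distance-quantile orders from
#' very local to the median distance.
#' @name bandwidth_defaults
#' @export
default_k_values <- function() c(5L, 10L, 15L, 20L, 25L, 30L)

#' @rdname bandwidth_defaults
#' @export
default_q_values <- function() c(0.02, 0.05, 0.1, 0.15, 0.2, 0.3, 0.5)

#' Leave-one-curve-out predictions over a candidate grid
#'
#' For each sample point `i` and each candidate, predicts \eqn{V_i} from the
#' remaining `n - 1` curves with the chosen estimator. Under `scope =
#' "local"` the candidates are the `k_values` and point `i`'s bandwidth for
#' candidate `k` is its own `k`-nearest-neighbour radius among the other
#' curves; under `scope = "global"` the candidates are bandwidths shared by
#' all points. Points whose neighbourhood is empty at a candidate get `NA`.
#'
#' @inheritParams conditional_quantile
#' @param predictor `"LM"` (L1-mode), `"ME"` (L1-median) or `"MO"`
#'   (density-based mode).
#' @param scope `"local"` or `"global"`.
#' @param k_values neighbour counts for the local scope.
#' @param q_values distance-quantile orders for the global scope.
#' @param control a [modal_control()] (used by `"LM"`).
#' @param pairwise optional precomputed [pairwise_distances()] matrix.
#' @return list with `predictions` (`n x n_candidate` matrix), `candidates`
#'   (for local scope, the `k_values`), `scope`, `bandwidths` (local scope:
#'   `n x n_candidate` matrix of per-point radii; global scope: the
#'   candidates).
#' @export
loo_predictions <- function(sample, sm, kernel = fkernel(),
                            predictor = c("LM", "ME", "MO"),
                            scope = c("local", "global"),
                            k_values = default_k_values(),
                            q_values = default_q_values(),
                            control = modal_control(),
                            pairwise = NULL) {
  predictor <- match.arg(predictor)
  scope <- match.arg(scope)
  if (is.null(sample$responses)) stop_invalid("sample has no responses")
  n <- n_curves(sample)
  V <- sample$responses
  if (is.null(pairwise)) pairwise <- pairwise_distances(sample, sm)

  if (scope == "local") {
    if (any(k_values > n - 1L))
      stop_invalid("k_values must be at most n - 1 for leave-one-out")
    candidates <- sort(as.integer(k_values))
  } else {
    candidates <- global_bandwidth_grid(pairwise, q_values)
  }
  C <- length(candidates)
  pred <- matrix(NA_real_, n, C)
  bw_used <- matrix(NA_real_, n, C)

  for (i in seq_len(n)) {
    d <- pairwise[-i, i]
    v <- V[-i]
    if (predictor == "MO") {
      # response kernel scale and search grid from the leave-out sample,
      # so the held-out response never influences its own prediction
      mo_bw_v <- stats::bw.nrd0(v)
      mo_grid <- seq(min(v), max(v), length.out = 201L)
    }
    bws <- if (scope == "local") local_bandwidth_grid(d, candidates)
           else candidates
    for (j in seq_len(C)) {
      w <- kernel_eval(kernel, d / bws[j])
      if (!any(w > 0)) next
      bw_used[i, j] <- bws[j]
      pred[i, j] <- switch(predictor,
        LM = mode_l1_wv(v, w, control),
        ME = median_wv(v, w),
        MO = mode_density_wv(v, w, mo_bw_v, mo_grid))
    }
  }
  list(predictions = pred, candidates = candidates, scope = scope,
       bandwidths = if (scope == "local") bw_used else candidates)
}

#' Cross-validation criterion and bandwidth selection
#'
#' `cv_from_predictions()` turns a leave-one-out prediction matrix into a CV
#' criterion per candidate — mean squared error (`"LS"`) or mean absolute
#' error (`"L1"`) over the points with valid predictions — and selects the
#' candidate minimizing it (ties toward the smallest candidate). Candidates
#' with no valid point get `Inf`. `loocv_select()` is the one-call driver:
#' leave-one-curve-out predictions plus selection.
#'
#' @param loo result of [loo_predictions()].
#' @param responses the observed responses.
#' @param loss_kind `"LS"` (squared error, the least-squares CV rule) or
#'   `"L1"` (absolute error, the quantile CV rule).
#' @return An object of class `"cv_result"`: list with `candidates`,
#'   `criterion` (mean loss), `criterion_sum`, `n_valid`, `selected`,
#'   `selected_index`, `scope`, `loss_kind`, `predictions`, `bandwidths`.
#' @export
cv_from_predictions <- function(loo, responses,
                                loss_kind = c("LS", "L1")) {
  loss_kind <- match.arg(loss_kind)
  err <- loo$predictions - responses
  loss <- if (loss_kind == "LS") err^2 else abs(err)
  n_valid <- colSums(!is.na(loss))
  crit_sum <- colSums(loss, na.rm = TRUE)
  crit <- ifelse(n_valid > 0, crit_sum / n_valid, Inf)
  if (all(!is.finite(crit)))
    stop(errorCondition("no candidate has a nonempty neighborhood at any point",
                        class = c("fmodal_selection_failed", "fmodal_error")))
  sel <- which.min(crit)  # candidates ascending: first minimum = smallest
  structure(list(candidates = loo$candidates, criterion = crit,
                 criterion_sum = crit_sum, n_valid = n_valid,
                 selected = loo$candidates[sel], selected_index = sel,
                 scope = loo$scope, loss_kind = loss_kind,
                 predictions = loo$predictions,
                 bandwidths = loo$bandwidths),
            class = "cv_result")
}

#' @rdname cv_from_predictions
#' @inheritParams loo_predictions
#' @export
loocv_select <- function(sample, sm, kernel = fkernel(),
                         predictor = c("LM", "ME", "MO"),
                         scope = c("local", "global"),
                         loss_kind = c("LS", "L1"),
                         k_values = default_k_values(),
                         q_values = default_q_values(),
                         control = modal_control(),
                         pairwise = NULL) {
  loo <- loo_predictions(sample, sm, kernel, predictor, scope,
                         k_values, q_values, control, pairwise)
  cv_from_predictions(loo, sample$responses, loss_kind)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s scope, %s loss: selected %s from %d candidates\n",
              x$scope, x$loss_kind, format(x$selected), length(x$candidates)))
  invisible(x)
}

#' Write a CV result to CSV (candidate, criterion, n_valid)
#'
#' @param cv a `cv_result`.
#' @param file output path.
#' @export
write_cv_result <- function(cv, file) {
  utils::write.csv(data.frame(candidate = cv$candidates,
                              criterion = cv$criterion,
                              n_valid = cv$n_valid),
                   file, row.names = FALSE)
  invisible(cv)
}

#' Predict responses at target curves with a fitted configuration
#'
#' Applies one of the three predictors at each target curve. For the local
#' scope `bandwidth` is interpreted as the neighbour count `k` and each
#' target uses its own `k`-nearest-neighbour radius among the sample curves;
#' for the global scope it is a single bandwidth shared by all targets.
#' Targets with an empty neighbourhood yield `NA`.
#'
#' @inheritParams loo_predictions
#' @param targets matrix of target curves (rows) on the sample's grid, or a
#'   single curve as a vector.
#' @param bandwidth neighbour count (`scope = "local"`) or bandwidth
#'   (`scope = "global"`).
#' @return numeric vector of predictions, one per target.
#' @export
predict_sample <- function(sample, sm, targets, bandwidth,
                           kernel = fkernel(),
                           predictor = c("LM", "ME", "MO"),
                           scope = c("local", "global"),
                           control = modal_control()) {
  predictor <- match.arg(predictor)
  scope <- match.arg(scope)
  if (is.null(sample$responses)) stop_invalid("sample has no responses")
  D <- cross_distances(sample, sm, targets)
  V <- sample$responses
  mo_bw_v <- if (predictor == "MO") stats::bw.nrd0(V) else NULL
  mo_grid <- if (predictor == "MO")
    seq(min(V), max(V), length.out = 201L) else NULL
  out <- rep(NA_real_, ncol(D))
  for (j in seq_len(ncol(D))) {
    d <- D[, j]
    bw <- if (scope == "local") local_bandwidth_grid(d, bandwidth) else bandwidth
    w <- kernel_eval(kernel, d / bw)
    if (!any(w > 0)) next
    out[j] <- switch(predictor,
      LM = mode_l1_wv(V, w, control),
      ME = median_wv(V, w),
      MO = mode_density_wv(V, w, mo_bw_v, mo_grid))
  }
  out
}
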