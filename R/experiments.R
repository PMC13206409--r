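#' Selector-comparison experiment (cross-validated prediction error table)
#'
#' Replicates the simulation benchmark comparing bandwidth selection rules:
#' for each replicate it simulates a two-regime heteroscedastic sample,
#' builds the PCA semi-metric, computes leave-one-curve-out predictions of
#' the L1-modal estimator over the local (k-NN) and global (distance
#' quantile) candidate grids, selects the bandwidth by the least-squares
#' (`LSCV`) and absolute-error (`QUCV`) rules, refits the estimator on the
#' full sample at the selected bandwidth, and records the mean squared
#' prediction error \eqn{MSE_{CV} = \frac{1}{n_k}\sum_{i \in S_k} (V_i -
#' \widetilde{LM}_{CV}(U_i))^2} per variability regime. Within a replicate
#' the curve sample and error draws are shared across SNR levels, scopes and
#' selectors, so differences between cells are attributable to the selector
#' alone.
#'
#' @param snr_levels signal-to-noise ratios (default the benchmark's
#'   `c(0.05, 0.1, 0.2, 0.3, 0.5)`).
#' @param scopes subset of `c("local", "global")`.
#' @param selectors subset of `c("LSCV", "QUCV")`.
#' @param replicates number of Monte-Carlo replicates (default 20), seeded
#'   `seed + 0 ... seed + replicates - 1`.
#' @param seed base integer seed.
#' @param config a [simulation_config()]; its `snr` field is overridden per
#'   level and its `seed` per replicate.
#' @param p PCA truncation of the semi-metric (default 3).
#' @param k_values,q_values candidate grids (see [local_bandwidth_grid()]).
#' @param kernel an [fkernel()].
#' @param control a [modal_control()].
#' @return an object of class `"experiment_report"`: list with `design`,
#'   `cells` (a data.frame of replicate-averaged cells with columns
#'   `regime`, `snr`, `scope`, `selector`, `mse`, `rmse`, `loo_mse`,
#'   `selected_mean`) and `per_replicate` (the raw per-replicate rows).
#' @export
run_selector_table <- function(snr_levels = c(0.05, 0.1, 0.2, 0.3, 0.5),
                               scopes = c("local", "global"),
                               selectors = c("LSCV", "QUCV"),
                               replicates = 20L, seed = 1L,
                               config = simulation_config(),
                               p = 3L,
                               k_values = default_k_values(),
                               q_values = default_q_values(),
                               kernel = fkernel(),
                               control = modal_control()) {
  scopes <- match.arg(scopes, several.ok = TRUE)
  selectors <- match.arg(selectors, several.ok = TRUE)
  loss_of <- c(LSCV = "LS", QUCV = "L1")
  rows <- list()
  for (rep_i in seq_len(replicates)) {
    cfg <- config
    cfg$seed <- as.integer(seed + rep_i - 1L)
    curves <- generate_curves(cfg)
    sm <- semimetric_pca(curves, p)
    D <- pairwise_distances(curves, sm)
    for (snr in snr_levels) {
      cfg$snr <- snr
      fs <- generate_responses(curves, cfg)
      for (scope in scopes) {
        loo <- loo_predictions(fs, sm, kernel, predictor = "LM",
                               scope = scope, k_values = k_values,
                               q_values = q_values, control = control,
                               pairwise = D)
        for (selector in selectors) {
          cv <- cv_from_predictions(loo, fs$responses, loss_of[[selector]])
          fit <- refit_predictions(fs, sm, kernel, D, scope, cv$selected,
                                   control)
          for (k in sort(unique(fs$regime))) {
            idx <- fs$regime == k
            err2 <- (fs$responses[idx] - fit[idx])^2
            loo_err2 <- (fs$responses[idx] -
                           loo$predictions[idx, cv$selected_index])^2
            rows[[length(rows) + 1L]] <- data.frame(
              replicate = rep_i, regime = k, snr = snr, scope = scope,
              selector = selector,
              mse = mean(err2, na.rm = TRUE),
              loo_mse = mean(loo_err2, na.rm = TRUE),
              selected = cv$selected)
          }
        }
      }
    }
  }
  per_replicate <- do.call(rbind, rows)
  cells <- stats::aggregate(
    cbind(mse, loo_mse, selected) ~ regime + snr + scope + selector,
    data = per_replicate, FUN = mean)
  names(cells)[names(cells) == "selected"] <- "selected_mean"
  cells$rmse <- sqrt(cells$mse)
  experiment_report(
    design = list(experiment = "selector_table", snr_levels = snr_levels,
                  scopes = scopes, selectors = selectors,
                  replicates = replicates, seed = seed, p = p,
                  k_values = k_values, q_values = q_values,
                  config = config),
    cells = cells, per_replicate = per_replicate)
}

# Full-sample refit of the L1-modal estimator at the selected bandwidth,
# evaluated at the observed curves (the printed MSE_CV formula). For the
# local scope `selected` is the neighbour count k and each point uses its
# k-NN radius among the *other* curves; its own weight (distance zero) is 1.
refit_predictions <- function(fs, sm, kernel, D, scope, selected, control) {
  n <- n_curves(fs)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    d <- D[, i]
    bw <- if (scope == "local") local_bandwidth_grid(D[-i, i], selected)
          else selected
    w <- kernel_eval(kernel, d / bw)
    if (!any(w > 0)) next
    out[i] <- mode_l1_wv(fs$responses, w, control)
  }
  out
}

#' Bandwidth-by-SNR error surface for the modal and median predictors
#'
#' On a stratified train/test split (default 300/100) evaluates the
#' out-of-sample mean squared error \eqn{MSE(d, SNR)} of the L1-modal
#' (`"LM"`) and L1-median (`"ME"`) predictors over a shared grid of global
#' bandwidths and a set of SNR levels. Both predictors see identical splits
#' and draws, so the surface differences are attributable to the estimator.
#'
#' @inheritParams run_selector_table
#' @param bandwidths optional bandwidth grid; default the global
#'   distance-quantile grid of the training curves.
#' @param predictors subset of `c("LM", "ME")`.
#' @param n_train training-set size of the stratified split.
#' @return an `"experiment_report"`; `cells` has columns `predictor`, `snr`,
#'   `bandwidth`, `mse`, `n_valid`, and `argmin` rows are flagged in
#'   `is_argmin`.
#' @export
run_mse_surface <- function(bandwidths = NULL,
                            snr_levels = c(0.05, 0.1, 0.2, 0.3, 0.5),
                            predictors = c("LM", "ME"),
                            seed = 1L,
                            config = simulation_config(),
                            p = 3L, n_train = 300L,
                            q_values = default_q_values(),
                            kernel = fkernel(),
                            control = modal_control()) {
  predictors <- match.arg(predictors, several.ok = TRUE)
  cfg <- config
  cfg$seed <- as.integer(seed)
  curves <- generate_curves(cfg)
  rows <- list()
  for (snr in snr_levels) {
    cfg$snr <- snr
    fs <- generate_responses(curves, cfg)
    split <- train_test_split(fs, n_train, stratified = TRUE, seed = seed)
    sm <- semimetric_pca(split$train, p)
    if (is.null(bandwidths)) {
      Dtr <- pairwise_distances(split$train, sm)
      bandwidths <- global_bandwidth_grid(Dtr, q_values)
    }
    for (pr in predictors) {
      for (bw in bandwidths) {
        pred <- predict_sample(split$train, sm, split$test$curves, bw,
                               kernel, predictor = pr, scope = "global",
                               control = control)
        err2 <- (split$test$responses - pred)^2
        rows[[length(rows) + 1L]] <- data.frame(
          predictor = pr, snr = snr, bandwidth = bw,
          mse = mean(err2, na.rm = TRUE), n_valid = sum(!is.na(err2)))
      }
    }
  }
  cells <- do.call(rbind, rows)
  cells$is_argmin <- stats::ave(cells$mse,
                                interaction(cells$predictor, cells$snr),
                                FUN = function(x) seq_along(x) == which.min(x)
                                ) == 1
  experiment_report(
    design = list(experiment = "mse_surface", snr_levels = snr_levels,
                  predictors = predictors, seed = seed, p = p,
                  n_train = n_train, config = config),
    cells = cells, per_replicate = cells)
}

#' Contamination robustness experiment
#'
#' Probes the breakdown behaviour of the three predictors: at each
#' contamination level `t` a fraction `floor(t * n_train)` of the training
#' responses is multiplied by a gross-error factor (default 10), the global
#' bandwidth is re-selected by least-squares cross-validation per predictor
#' on the contaminated training set, and the test-set mean squared and mean
#' absolute errors are recorded. The quantile-based predictors (mode and
#' median) are expected to move far less across levels than the
#' density-based mode.
#'
#' @inheritParams run_selector_table
#' @param levels contamination proportions, ascending, starting at 0.
#' @param predictors subset of `c("LM", "ME", "MO")`.
#' @param factor gross-error multiplier.
#' @param n_train training-set size of the stratified split.
#' @return an `"experiment_report"`; `cells` has replicate-averaged columns
#'   `level`, `predictor`, `mse`, `mae`; `per_replicate` the raw rows.
#' @export
run_contamination <- function(levels = seq(0, 0.5, by = 0.1),
                              predictors = c("LM", "ME", "MO"),
                              replicates = 20L, seed = 1L,
                              config = simulation_config(n1 = 100L, n2 = 100L),
                              factor = 10, p = 3L, n_train = 150L,
                              q_values = default_q_values(),
                              kernel = fkernel(),
                              control = modal_control()) {
  predictors <- match.arg(predictors, several.ok = TRUE)
  if (is.unsorted(levels) || levels[1] != 0)
    stop_invalid("levels must be ascending and start at 0")
  rows <- list()
  for (rep_i in seq_len(replicates)) {
    cfg <- config
    cfg$seed <- as.integer(seed + rep_i - 1L)
    fs <- simulate_heteroscedastic(cfg)
    split <- train_test_split(fs, n_train, stratified = TRUE, seed = cfg$seed)
    sm <- semimetric_pca(split$train, p)
    Dtr <- pairwise_distances(split$train, sm)
    for (lv in levels) {
      spec <- contamination_spec(lv, factor, seed = cfg$seed + 7L)
      train <- split$train
      train$responses <- contaminate(train$responses, spec)
      for (pr in predictors) {
        cv <- loocv_select(train, sm, kernel, predictor = pr,
                           scope = "global", loss_kind = "LS",
                           q_values = q_values, control = control,
                           pairwise = Dtr)
        pred <- predict_sample(train, sm, split$test$curves, cv$selected,
                               kernel, predictor = pr, scope = "global",
                               control = control)
        err <- split$test$responses - pred
        rows[[length(rows) + 1L]] <- data.frame(
          replicate = rep_i, level = lv, predictor = pr,
          mse = mean(err^2, na.rm = TRUE),
          mae = mean(abs(err), na.rm = TRUE),
          n_valid = sum(!is.na(err)), selected = cv$selected)
      }
    }
  }
  per_replicate <- do.call(rbind, rows)
  cells <- stats::aggregate(cbind(mse, mae) ~ level + predictor,
                            data = per_replicate, FUN = mean)
  experiment_report(
    design = list(experiment = "contamination", levels = levels,
                  predictors = predictors, replicates = replicates,
                  seed = seed, factor = factor, p = p, n_train = n_train,
                  config = config),
    cells = cells, per_replicate = per_replicate)
}

experiment_report <- function(design, cells, per_replicate) {
  structure(list(design = design, cells = cells,
                 per_replicate = per_replicate),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %s: %d cells\n",
              x$design$experiment, nrow(x$cells)))
  print(utils::head(x$cells, 12))
  invisible(x)
}

#' Write an experiment report as tidy CSV plus a run manifest
#'
#' Writes `cells` to `file`, the raw per-replicate rows next to it
#' (`*_replicates.csv`), and a plain-text manifest of the design
#' (`*_manifest.txt`) so every run is reproducible from its outputs.
#'
#' @param report an `"experiment_report"`.
#' @param file output CSV path.
#' @export
write_experiment_report <- function(report, file) {
  utils::write.csv(report$cells, file, row.names = FALSE)
  stem <- sub("\\.csv$", "", file)
  utils::write.csv(report$per_replicate,
                   paste0(stem, "_replicates.csv"), row.names = FALSE)
  design <- report$design
  flat <- vapply(names(design), function(nm) {
    val <- design[[nm]]
    if (inherits(val, "simulation_config"))
      val <- paste(names(unclass(val)), unlist(val), sep = "=", collapse = " ")
    paste0(nm, ": ", paste(format(val), collapse = ", "))
  }, character(1))
  writeLines(flat, paste0(stem, "_manifest.txt"))
  invisible(report)
}
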