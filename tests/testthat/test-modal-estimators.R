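test_that("mode extraction obeys the smallest-order tie-break", {
  qc <- structure(list(orders = c(0.2, 0.5, 0.8),
                       values = c(1, 2, 3),
                       derivatives = c(4, 4, 4),
                       step = 0.05, interval = c(0.2, 0.8),
                       n_effective = 10L),
                  class = "quantile_curve")
  fit <- mode_from_quantile_curve(qc)
  expect_equal(fit$t_star, 0.2)
  expect_equal(fit$mode, 1)
  expect_equal(fit$derivative_min, 4)
})

test_that("Gaussian conditional law: t* near 0.5, mode near the mean", {
  # normal quantile density sigma / phi(qnorm(t)) is minimized at t = 0.5
  set.seed(21)
  mu <- 1.5; sigma <- 0.5
  v <- rnorm(2000, mu, sigma)
  fs <- functional_sample(c(0, 1), matrix(0, 2000, 2), responses = v)
  # a wider difference-quotient step stabilizes the argmin of the flat
  # quantile density near its minimum
  fit <- predict_mode_l1(fs, c(0, 0), bandwidth = 1,
                         sm = semimetric_l2(c(0, 1)),
                         kernel = fkernel("uniform"),
                         control = modal_control(interval = c(0.2, 0.8),
                                                 step = 0.12))
  expect_lt(abs(fit$t_star - 0.5), 0.1)
  expect_lt(abs(fit$mode - mu), 0.1)
})

test_that("right-skewed conditional law pushes the mode below the median", {
  # log-normal: mode exp(mu - s^2) < median exp(mu)
  set.seed(22)
  v <- rlnorm(4000, meanlog = 0, sdlog = 0.6)
  fs <- functional_sample(c(0, 1), matrix(0, 4000, 2), responses = v)
  sm <- semimetric_l2(c(0, 1))
  fit <- predict_mode_l1(fs, c(0, 0), bandwidth = 1, sm = sm,
                         kernel = fkernel("uniform"))
  med <- predict_median(fs, c(0, 0), bandwidth = 1, sm = sm,
                        kernel = fkernel("uniform"))
  expect_lt(fit$mode, med)
  # and it should sit nearer the true mode than the median does
  true_mode <- exp(-0.36)
  expect_lt(abs(fit$mode - true_mode), abs(med - true_mode))
})

test_that("the L1-median equals the conditional quantile at order 0.5", {
  fs <- toy_sample(n = 25, m = 15, seed = 12)
  sm <- semimetric_pca(fs, 2)
  D <- pairwise_distances(fs, sm)
  bw <- stats::median(D[upper.tri(D)])
  for (i in c(1, 7, 20)) {
    me <- predict_median(fs, fs$curves[i, ], bw, sm)
    expect_identical(me, conditional_quantile(fs, fs$curves[i, ], 0.5, bw, sm))
  }
  # equal weights, odd n: the sample median
  unif <- fkernel("uniform")
  expect_equal(predict_median(fs, fs$curves[1, ], 1e6, sm, unif),
               unname(stats::quantile(fs$responses, 0.5, type = 1)))
  # matches brute-force minimization of the weighted absolute loss
  w <- kernel_weights(D[, 5], bw)$weights
  keep <- w > 0
  expect_lt(abs(predict_median(fs, fs$curves[5, ], bw, sm) -
                brute_force_weighted_quantile(fs$responses[keep],
                                              w[keep], 0.5)), 1.5e-4)
})

test_that("density-based mode: degenerate and single-neighbour cases", {
  g <- c(0, 1)
  fs <- functional_sample(g, matrix(c(0, 0, 10, 10, 20, 20), 3, 2,
                                    byrow = TRUE),
                          responses = c(5, 5, 5))
  sm <- semimetric_l2(g)
  # all responses equal c with c on the grid -> c
  expect_equal(predict_mode_density(fs, c(0, 0), bandwidth_x = 1e3,
                                    bandwidth_v = 1, sm = sm,
                                    v_grid = seq(0, 10, by = 0.5)), 5)
  # single positive x-weight -> grid point nearest that response
  fs2 <- functional_sample(g, fs$curves, responses = c(1.26, 8, 9))
  got <- predict_mode_density(fs2, c(0, 0), bandwidth_x = 5,
                              bandwidth_v = 0.5, sm = sm,
                              v_grid = seq(0, 10, by = 0.1))
  expect_equal(got, 1.3)
})

test_that("density-based mode matches a refined-grid search", {
  set.seed(30)
  fs <- toy_sample(n = 20, m = 12, seed = 30)
  sm <- semimetric_pca(fs, 2)
  D <- pairwise_distances(fs, sm)
  bw_x <- unname(stats::quantile(D[upper.tri(D)], 0.5))
  bw_v <- stats::bw.nrd0(fs$responses)
  coarse <- seq(min(fs$responses), max(fs$responses), length.out = 101)
  fine <- seq(min(fs$responses), max(fs$responses), length.out = 1001)
  got <- predict_mode_density(fs, fs$curves[4, ], bw_x, bw_v, sm,
                              v_grid = coarse)
  ref <- predict_mode_density(fs, fs$curves[4, ], bw_x, bw_v, sm,
                              v_grid = fine)
  expect_lt(abs(got - ref), diff(coarse[1:2]) + 1e-12)
})

test_that("all three predictors are affine-equivariant in the response", {
  fs <- toy_sample(n = 30, m = 12, seed = 31)
  sm <- semimetric_pca(fs, 2)
  D <- pairwise_distances(fs, sm)
  bw <- unname(stats::quantile(D[upper.tri(D)], 0.3))
  a <- 1.7; b <- -2
  fs2 <- functional_sample(fs$grid, fs$curves,
                           responses = a * fs$responses + b)
  tgt <- fs$curves[9, ]
  expect_equal(predict_mode_l1(fs2, tgt, bw, sm)$mode,
               a * predict_mode_l1(fs, tgt, bw, sm)$mode + b)
  expect_equal(predict_median(fs2, tgt, bw, sm),
               a * predict_median(fs, tgt, bw, sm) + b)
  # MO: rescale the response bandwidth and map the search grid through the
  # same affine map so the discrete argmax transforms exactly
  v_grid <- seq(min(fs$responses), max(fs$responses), length.out = 201)
  bw_v <- stats::bw.nrd0(fs$responses)
  expect_equal(predict_mode_density(fs2, tgt, bw, a * bw_v, sm,
                                    v_grid = a * v_grid + b),
               a * predict_mode_density(fs, tgt, bw, bw_v, sm,
                                        v_grid = v_grid) + b)
})

test_that("mode and median agree asymptotically under a symmetric law", {
  gap_at <- function(n, seed) {
    cfg <- simulation_config(n1 = n / 2, n2 = n / 2, snr = 0.2, seed = seed)
    fs <- simulate_heteroscedastic(cfg)
    sm <- semimetric_pca(fs, 3)
    D <- pairwise_distances(fs, sm)
    gaps <- vapply(1:15, function(i) {
      bw <- local_bandwidth_grid(D[-i, i], min(60, n / 4))
      w <- kernel_eval(fkernel(), D[, i] / bw)
      abs(fmodal:::mode_l1_wv(fs$responses, w, modal_control()) -
          fmodal:::median_wv(fs$responses, w))
    }, numeric(1))
    mean(gaps)
  }
  gaps_small <- vapply(1:5, function(s) gap_at(200, s), numeric(1))
  gaps_large <- vapply(1:5, function(s) gap_at(800, s + 100), numeric(1))
  expect_lt(mean(gaps_large), mean(gaps_small))
})
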