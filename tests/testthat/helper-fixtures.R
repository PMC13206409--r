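# Small fixtures built in code, shared across test files.

toy_grid <- function(m = 5) seq(0, 1, length.out = m)

# A tiny deterministic functional sample with responses.
toy_sample <- function(n = 10, m = 20, seed = 42, responses = TRUE) {
  set.seed(seed)
  grid <- seq(0, 1, length.out = m)
  a <- rnorm(n); b <- rnorm(n)
  curves <- outer(a, sin(2 * pi * grid)) + outer(b, rep(1, m)) +
    matrix(rnorm(n * m, sd = 0.1), n, m)
  functional_sample(grid, curves,
                    responses = if (responses) a + 0.5 * b + rnorm(n, sd = 0.1))
}

# Brute-force minimizer of the weighted check loss over a dense grid of s;
# the independent oracle for the closed-form weighted quantile. Ties resolve
# to the smallest minimizer because which.min takes the first.
brute_force_weighted_quantile <- function(values, weights, order,
                                          grid_step = 1e-4) {
  s_grid <- seq(min(values), max(values), by = grid_step)
  obj <- vapply(s_grid, function(s)
    sum(weights * check_loss(order, values - s)), numeric(1))
  s_grid[which.min(obj)]
}

# Environment-level cache so expensive seeded computations are shared
# between test blocks instead of recomputed.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}
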