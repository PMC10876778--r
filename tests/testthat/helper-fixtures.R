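# small in-code fixtures shared across test files

tiny_volume <- function(dims = c(4, 4, 4), nt = 20, tr = 2, seed = 1,
                        voxel_mm = 3) {
  set.seed(seed)
  ts_volume(array(rnorm(prod(dims) * nt), dim = c(dims, nt)),
            centered_affine(dims, voxel_mm), tr)
}

# volume whose every voxel carries the same time series
uniform_series_volume <- function(series, dims = c(4, 4, 4), tr = 2) {
  arr <- array(rep(series, each = prod(dims)), dim = c(dims, length(series)))
  ts_volume(arr, centered_affine(dims), tr)
}

full_mask <- function(dims = c(4, 4, 4)) array(TRUE, dim = dims)

# independent oracle for Kendall's W via the Friedman statistic
# (W = Q / (K * (n - 1)); valid for tie-free data)
friedman_w <- function(x) {
  k <- nrow(x); n <- ncol(x)
  unname(stats::friedman.test(x)$statistic) / (k * (n - 1))
}

# brute-force single-sided DFT amplitude at 1-based bin b (DC = 1),
# by explicit summation under the package's 2|X_k|/n convention
brute_amplitude <- function(x, b) {
  n <- length(x)
  kk <- b - 1
  re <- sum(x * cos(-2 * pi * kk * (0:(n - 1)) / n))
  im <- sum(x * sin(-2 * pi * kk * (0:(n - 1)) / n))
  2 * sqrt(re^2 + im^2) / n
}

expect_map_equal <- function(a, b, tol = 1e-12) {
  expect_equal(as.numeric(a$data), as.numeric(b$data), tolerance = tol)
}
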