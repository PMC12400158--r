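# Shared fixtures and independent oracles used across the test files.

# analytic Gaussian chromatogram: peaks given as (time, area) pairs
gaussian_chrom <- function(centers, areas, sigma = 0.05, baseline = 0,
                           from = 0, to = NULL, step = sigma / 10) {
  if (is.null(to)) to <- max(centers) + 20 * sigma
  t <- seq(from, to, by = step)
  y <- rep(baseline, length(t))
  for (k in seq_along(centers)) {
    y <- y + areas[k] / (sigma * sqrt(2 * pi)) *
      exp(-(t - centers[k])^2 / (2 * sigma^2))
  }
  chromatogram(t, y)
}

# brute-force PCA oracle: eigendecomposition of the covariance matrix
pca_eigen_oracle <- function(X) {
  ev <- eigen(stats::cov(X), symmetric = TRUE)
  n <- nrow(X)
  # singular values of the centred matrix relate via d^2 = (n-1) * lambda
  list(values = ev$values, vectors = ev$vectors)
}

# brute-force ordinary least squares via the normal equations
ols_oracle <- function(x, y) {
  A <- cbind(1, x)
  drop(solve(t(A) %*% A, t(A) %*% y))
}

planted_marker_peaks <- c("2", "8", "9", "10", "11", "12", "17")

default_match_template <- function(tolerance = 0.02) {
  info <- default_peak_info()
  rrt_template(stats::setNames(info$rrt, info$peak_id),
               reference_peak = "11", reference_time = 12,
               tolerance = tolerance)
}
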