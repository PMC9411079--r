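# In-code fixtures shared across test files.

gauss <- function(x, x0, sigma, h) h * exp(-(x - x0)^2 / (2 * sigma^2))

# Spectrum from a plain intensity vector on a uniform 1-mDa grid
spectrum_from_intensity <- function(intensity, mz = NULL, ...) {
  if (is.null(mz)) mz <- 100 + seq_along(intensity) * 1e-3
  new_spectrum(mz, intensity, ...)
}

# PeakProfile built directly, bypassing isolation
make_profile <- function(mz, intensity, scan_id = "s1", scan_index = 1L) {
  structure(list(mz = mz, intensity = intensity, start = 1L,
                 end = length(mz), split_left = FALSE, split_right = FALSE,
                 scan_id = scan_id, scan_index = scan_index,
                 ms_level = 1L, retention_time = NA_real_),
            class = "PeakProfile")
}

# RegressionResult built directly, for backtransform unit tests
make_result <- function(beta, cov_beta = matrix(0, 3, 3), x_shift = 0,
                        mse = 0, dof = 4L, n_points = 7L) {
  structure(list(beta = beta, cov_beta = cov_beta, mse = mse, dof = dof,
                 nrmse = 0, x_shift = x_shift, n_points = n_points),
            class = "RegressionResult")
}

# unweighted iterative non-linear Gaussian fit: the independent oracle
nls_gauss_oracle <- function(mz, intensity) {
  m0 <- sum(mz * intensity) / sum(intensity)
  s0 <- sqrt(sum(intensity * (mz - m0)^2) / sum(intensity))
  fit <- minpack.lm::nlsLM(
    I ~ h * exp(-(x - mu)^2 / (2 * s^2)),
    data = data.frame(x = mz, I = intensity),
    start = list(h = max(intensity), mu = m0, s = s0),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  as.list(stats::coef(fit))
}

# erf by numerical integration of its defining integral
erf_integral <- function(x) {
  2 / sqrt(pi) * stats::integrate(function(t) exp(-t^2), 0, x,
                                  rel.tol = 1e-12)$value
}
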