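test_that("weights are intensity shares raised to the power", {
  expect_equal(compute_weights(c(1, 1, 2)), c(0.0625, 0.0625, 0.25))
  expect_equal(compute_weights(5), 1)
  expect_equal(compute_weights(rep(3.7, 4)), rep(0.0625, 4))
  expect_equal(compute_weights(c(1, 3), weight_power = 0), c(1, 1))
  expect_error(compute_weights(numeric(0)), "empty")
  expect_error(compute_weights(c(1, 0)), "positive")
})

test_that("log of a Gaussian is recovered as the exact parabola", {
  x <- 100 + (-3:3) * 1e-3   # grid offset keeps the shift path honest
  p <- make_profile(x, 1000 * exp(-((x - 100) / 1e-3)^2 / 2))
  r <- fit_profiles(list(p))[[1]]
  expect_s3_class(r, "RegressionResult")
  # beta in centered coordinates; apex = center here
  expect_equal(r$beta[1], log(1000), tolerance = 1e-12)
  expect_equal(r$beta[2], 0, tolerance = 1e-6)
  expect_equal(r$beta[3], -0.5 / 1e-6, tolerance = 1e-9)
  expect_lt(r$mse, 1e-18)
  expect_identical(r$dof, 4L)
})

test_that("4 noiseless points recover the Gaussian to 1e-9 and match the non-linear oracle", {
  x <- c(199.997, 199.999, 200.001, 200.003)
  I <- gauss(x, 200, 0.002, 1e6)
  p <- make_profile(x, I)
  g <- backtransform(fit_profiles(list(p))[[1]])
  expect_s3_class(g, "GaussianPeak")
  expect_equal(g$x0, 200, tolerance = 1e-9)
  expect_equal(g$sigma, 0.002, tolerance = 1e-9)
  expect_equal(g$height, 1e6, tolerance = 1e-9)
  oracle <- nls_gauss_oracle(x, I)
  expect_equal(g$x0, oracle$mu, tolerance = 1e-9)
  expect_equal(g$sigma, oracle$s, tolerance = 1e-7)
})

test_that("profiles below the minimum point count are rejected, not fitted", {
  p3 <- make_profile(c(1, 2, 3) * 1e-3 + 100, c(1, 5, 2))
  r <- fit_profiles(list(p3))[[1]]
  expect_s3_class(r, "RejectRecord")
  expect_identical(r$reason, "min_points")
})

test_that("backtransform reproduces the closed-form parameter map", {
  g <- backtransform(make_result(c(log(100), 0, -0.5)))
  expect_equal(g$x0, 0)
  expect_equal(g$sigma, 1)
  expect_equal(g$height, 100)
  expect_equal(g$area, 100 * sqrt(2 * pi), tolerance = 1e-12)

  g2 <- backtransform(make_result(c(0, 2, -1)))
  expect_equal(g2$x0, 1)
  expect_equal(g2$sigma, sqrt(0.5), tolerance = 1e-12)
  expect_equal(g2$height, exp(1), tolerance = 1e-12)

  r <- backtransform(make_result(c(1, 0, 0.1)))
  expect_s3_class(r, "RejectRecord")
  expect_identical(r$reason, "beta2_nonneg")

  g3 <- backtransform(make_result(c(log(100), 0, -0.5)))  # zero covariance
  expect_identical(c(g3$d_height, g3$d_sigma, g3$d_area), c(0, 0, 0))
})

test_that("coefficients and covariance agree with weighted lm", {
  tr <- generate_spectrum(n_peaks = 1, noise_cv = 0.02, seed = 5)
  p <- isolate_profiles(tr$spectrum)[[1]]
  f <- fit_profiles(list(p))[[1]]
  u <- p$mz - p$mz[which.max(p$intensity)]
  lmf <- stats::lm(log(p$intensity) ~ u + I(u^2),
                   weights = compute_weights(p$intensity))
  expect_equal(f$beta, unname(stats::coef(lmf)), tolerance = 1e-9)
  expect_equal(f$cov_beta, unname(stats::vcov(lmf)), tolerance = 1e-9)
  expect_equal(f$mse, summary(lmf)$sigma^2, tolerance = 1e-9)
  expect_equal(f$nrmse, sqrt(f$mse) / mean(log(p$intensity)),
               tolerance = 1e-12)
})

test_that("noiseless Gaussians of any size and scale are recovered exactly", {
  set.seed(77)
  for (k in 1:40) {
    n <- sample(4:20, 1)
    x0 <- runif(1, 100, 1000)
    sigma <- orbitrap_width_model(x0)
    h <- 10^runif(1, 3, 8)
    x <- x0 + seq(-2.5, 2.5, length.out = n) * sigma + runif(1, -0.3, 0.3) * sigma
    p <- make_profile(x, gauss(x, x0, sigma, h))
    g <- backtransform(fit_profiles(list(p))[[1]])
    expect_equal(g$x0, x0, tolerance = 1e-9)
    expect_equal(g$sigma, sigma, tolerance = 1e-9)
    expect_equal(g$height, h, tolerance = 1e-9)
  }
})

test_that("fits are scale- and shift-equivariant", {
  set.seed(3)
  x <- 200 + seq(-3, 3) * 1.1e-3
  I <- gauss(x, 200.0004, 0.0013, 5e5) * exp(rnorm(7, 0, 0.01))
  g <- backtransform(fit_profiles(list(make_profile(x, I)))[[1]])
  gc <- backtransform(fit_profiles(list(make_profile(x, I * 1000)))[[1]])
  expect_equal(gc$x0, g$x0, tolerance = 1e-12)
  expect_equal(gc$sigma, g$sigma, tolerance = 1e-12)
  expect_equal(gc$height, g$height * 1000, tolerance = 1e-12)
  expect_equal(gc$area, g$area * 1000, tolerance = 1e-12)
  gs <- backtransform(fit_profiles(list(make_profile(x + 5, I)))[[1]])
  expect_equal(gs$x0, g$x0 + 5, tolerance = 1e-9)
  expect_equal(gs$sigma, g$sigma, tolerance = 1e-9)
  expect_equal(gs$height, g$height, tolerance = 1e-9)
})

test_that("blocked sparse solve equals per-profile solves", {
  tr <- generate_spectrum(n_peaks = 40, noise_cv = 0.01, seed = 9)
  prof <- isolate_profiles(tr$spectrum)
  f1 <- fit_profiles(prof, method = "per_profile")
  f2 <- fit_profiles(prof, method = "blocked")
  for (i in seq_along(f1)) {
    expect_equal(f2[[i]]$beta, f1[[i]]$beta, tolerance = 1e-9)
    expect_equal(f2[[i]]$cov_beta, f1[[i]]$cov_beta, tolerance = 1e-9)
    expect_equal(f2[[i]]$mse, f1[[i]]$mse, tolerance = 1e-9)
  }
  # short profiles are rejected identically on both paths
  prof3 <- c(prof[1:2], list(make_profile(c(1, 2, 3) * 1e-3 + 100, c(1, 5, 2))))
  f3 <- fit_profiles(prof3, method = "blocked")
  expect_s3_class(f3[[3]], "RejectRecord")
  expect_identical(f3[[3]]$reason, "min_points")
})
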