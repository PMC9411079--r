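test_that("width model reproduces the nominal resolving power", {
  expect_equal(fwhm_from_sigma(orbitrap_width_model(200)), 200 / 70000,
               tolerance = 1e-12)
  # R(800) = 70000 * (200/800)^0.5 = 35000
  expect_equal(fwhm_from_sigma(orbitrap_width_model(800)), 800 / 35000,
               tolerance = 1e-12)
  expect_error(orbitrap_width_model(-5), "> 0")
})

test_that("noiseless generation, isolation, fit and score close the exactness chain", {
  tr <- generate_spectrum(peaks = data.frame(x0 = 200, height = 1e6),
                          noise_cv = 0, points_per_fwhm = 3, seed = 4)
  expect_identical(tr$noise_cv, 0)
  cent <- centroid_spectrum(tr$spectrum)$centroids
  expect_identical(nrow(cent), 1L)
  expect_equal(cent$mz_centroid, 200, tolerance = 1e-9)
  expect_equal(cent$sigma, tr$peaks$sigma, tolerance = 1e-9)
  expect_equal(cent$height, 1e6, tolerance = 1e-9)
  expect_equal(cent$dqs, 1, tolerance = 1e-12)
})

test_that("sampled intensities equal the model exactly when noise is off", {
  tr <- generate_spectrum(peaks = data.frame(x0 = 300, sigma = 0.002,
                                             height = 5e5),
                          noise_cv = 0, seed = 2)
  sp <- tr$spectrum
  nz <- sp$intensity > 0
  expect_equal(sp$intensity[nz],
               gauss(sp$mz[nz], 300, 0.002, 5e5), tolerance = 1e-12)
  # zero-flanked: first and last points of the run are zeros
  expect_identical(sp$intensity[1], 0)
  expect_identical(sp$intensity[length(sp$intensity)], 0)
})

test_that("default grid density gives Orbitrap-like profiles of ~5-9 points", {
  counts <- integer(0)
  for (s in 1:5) {
    tr <- generate_spectrum(n_peaks = 200, noise_cv = 0, seed = 400 + s)
    counts <- c(counts, vapply(isolate_profiles(tr$spectrum),
                               function(p) length(p$mz), integer(1)))
  }
  expect_length(counts, 1000)
  expect_gte(mean(counts), 5)
  expect_lte(mean(counts), 9)
  expect_true(all(counts >= 4))
})

test_that("generation is deterministic for a fixed seed", {
  a <- generate_spectrum(n_peaks = 20, noise_cv = 0.02, seed = 123)
  b <- generate_spectrum(n_peaks = 20, noise_cv = 0.02, seed = 123)
  expect_identical(a$spectrum$mz, b$spectrum$mz)
  expect_identical(a$spectrum$intensity, b$spectrum$intensity)
  expect_identical(a$peaks, b$peaks)
})

test_that("noisy noiseless centroids sit within an Orbitrap-like ppm error", {
  set.seed(42)
  acc <- numeric(0)
  for (r in 1:100) {
    tr <- generate_spectrum(peaks = data.frame(x0 = 200, height = 1e6),
                            noise_cv = 0.01, seed = NULL)
    cent <- centroid_spectrum(tr$spectrum)$centroids
    if (nrow(cent) == 1)
      acc <- c(acc, mass_accuracy_ppm(cent$mz_centroid, 200))
  }
  expect_gt(length(acc), 90)
  expect_lte(median(abs(acc)), 0.5)
})

test_that("overlapping pairs merge into one fitted profile with a lower score", {
  sigma <- orbitrap_width_model(200)
  sep <- c(6, 1.2)
  out <- lapply(sep, function(s) {
    tr <- generate_spectrum(peaks = data.frame(
      x0 = 200 + c(-0.5, 0.5) * s * sigma, sigma = sigma, height = 1e6),
      noise_cv = 0.01, seed = 55)
    centroid_spectrum(tr$spectrum)$centroids
  })
  expect_identical(nrow(out[[1]]), 2L)   # resolved pair
  expect_identical(nrow(out[[2]]), 1L)   # merged pair, no valley
  expect_lt(out[[2]]$dqs, max(out[[1]]$dqs))
})

test_that("overlap experiment summarizes DQS per separation", {
  tab <- overlap_experiment(separations = c(6, 3), n_rep = 10,
                            noise_cv = 0.01, seed = 77)
  expect_identical(nrow(tab), 2L)
  expect_true(all(tab$n_centroids == 20))
  expect_true(all(tab$mean_dqs > 0 & tab$mean_dqs <= 1))
  expect_gt(tab$mean_dqs[tab$separation == 6],
            tab$mean_dqs[tab$separation == 3])
})
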