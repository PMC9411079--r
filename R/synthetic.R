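# Synthetic profile spectra with known ground truth: Gaussian peaks whose
# widths follow an Orbitrap-like resolving-power law, sampled on sparse
# local grids, with optional multiplicative noise and controlled overlaps.

#' Orbitrap-like peak width model
#'
#' Resolving power of an Orbitrap falls off with the square root of mass:
#' `R(m) = r_ref * (200 / m)^exponent`, anchored at a nominal resolution
#' `r_ref` at m/z 200 (default 70000, a common full-scan MS1 setting).
#' The peak width follows as `FWHM = m / R(m)` and
#' `sigma = FWHM / (2 sqrt(2 ln 2))`.
#'
#' @param mz m/z value(s), > 0.
#' @param r_ref Nominal resolution at m/z 200 (default 70000).
#' @param exponent Power-law decay exponent (default 0.5).
#' @return Peak standard deviation(s) `sigma` in m/z units.
#' @examples
#' fwhm_from_sigma(orbitrap_width_model(200))  # 200 / 70000
#' @export
orbitrap_width_model <- function(mz, r_ref = 70000, exponent = 0.5) {
  if (any(mz <= 0)) stop("mz must be > 0")
  if (r_ref <= 0) stop("r_ref must be > 0")
  fwhm <- mz / (r_ref * (200 / mz)^exponent)
  sigma_from_fwhm(fwhm)
}

#' Generate a synthetic profile spectrum with ground truth
#'
#' Builds one profile-mode spectrum from a list of Gaussian peaks. Each
#' group of mutually overlapping peaks is sampled on a shared uniform m/z
#' grid (step `FWHM / points_per_fwhm`, random grid phase) over an
#' extension of `window_sigma` standard deviations around the peak
#' centers; sampled intensities below `intensity_floor` are set to zero
#' (the detector floor), and every sampled run is flanked by explicit zero
#' points, mimicking how resolved Orbitrap profiles are surrounded by
#' zeros. Multiplicative log-normal noise `I * exp(eps)`,
#' `eps ~ N(0, noise_cv)`, models intensity scatter; `noise_cv = 0` yields
#' exact model values.
#'
#' @param peaks Data frame with columns `x0`, `height` and optionally
#'   `sigma` (missing widths are filled from the width model), or `NULL`
#'   to draw `n_peaks` random peaks.
#' @param n_peaks Number of random peaks when `peaks` is `NULL`: positions
#'   uniform over `mz_range`, heights log-uniform over `height_range`,
#'   widths from the width model.
#' @param ensure_separated For random peaks only: redraw positions whose
#'   sampling windows would overlap a neighbour's, so that every generated
#'   peak yields exactly one isolated profile (default `TRUE`). Explicit
#'   `peaks` are never moved, so controlled overlaps remain possible.
#' @param mz_range,height_range Ranges for random peaks (defaults
#'   m/z 100--1000, heights 1e4--1e7).
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (default 0 = noiseless).
#' @param points_per_fwhm Grid density (default 2.7, giving profiles of
#'   about 6--7 points, mean ~6.9, as typical for Orbitrap full scans).
#' @param seed Integer seed (Mersenne-Twister via [set.seed()]); `NULL`
#'   continues the caller's random stream.
#' @param window_sigma Half-width of the sampling window per peak in
#'   multiples of sigma (default 3; beyond it profiles are zero-filled).
#' @param intensity_floor Counts below this are recorded as zero
#'   (default 1).
#' @param r_ref,exponent Width-model parameters, see
#'   [orbitrap_width_model()].
#' @param scan_id,scan_index,retention_time Metadata for the generated
#'   spectrum.
#' @return A `SyntheticTruth`: list with `peaks` (ground-truth data frame
#'   `x0`, `sigma`, `height`), `spectrum` (a `Spectrum`), and the
#'   generator settings.
#' @examples
#' tr <- generate_spectrum(n_peaks = 5, seed = 42)
#' length(isolate_profiles(tr$spectrum))  # 5 well-separated profiles
#' @export
generate_spectrum <- function(peaks = NULL, n_peaks = 10,
                              mz_range = c(100, 1000),
                              height_range = c(1e4, 1e7),
                              noise_cv = 0, points_per_fwhm = 2.7,
                              seed = NULL, ensure_separated = TRUE,
                              window_sigma = 3,
                              intensity_floor = 1,
                              r_ref = 70000, exponent = 0.5,
                              scan_id = "synthetic=1", scan_index = 1L,
                              retention_time = NA_real_) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(peaks)) {
    x0 <- sort(stats::runif(n_peaks, mz_range[1], mz_range[2]))
    if (ensure_separated && n_peaks > 1L) {
      # redraw positions whose +-window_sigma sampling windows (plus one
      # grid step of slack) would touch a neighbour's
      for (iter in 1:200) {
        w <- (window_sigma + 2 * sqrt(2 * log(2)) / points_per_fwhm) *
          orbitrap_width_model(x0, r_ref, exponent)
        bad <- which(c(FALSE, diff(x0) < (w[-n_peaks] + w[-1])))
        if (!length(bad)) break
        x0[bad] <- stats::runif(length(bad), mz_range[1], mz_range[2])
        x0 <- sort(x0)
      }
    }
    peaks <- data.frame(
      x0 = x0,
      sigma = orbitrap_width_model(x0, r_ref, exponent),
      height = 10^stats::runif(n_peaks, log10(height_range[1]),
                               log10(height_range[2])))
  } else {
    peaks <- as.data.frame(peaks)
    if (is.null(peaks$sigma))
      peaks$sigma <- orbitrap_width_model(peaks$x0, r_ref, exponent)
    peaks <- peaks[order(peaks$x0), , drop = FALSE]
  }
  stopifnot(all(peaks$height > 0), all(peaks$sigma > 0),
            points_per_fwhm > 0)
  np <- nrow(peaks)
  lo <- peaks$x0 - window_sigma * peaks$sigma
  hi <- peaks$x0 + window_sigma * peaks$sigma
  # chain peaks whose sampling windows overlap into clusters
  cluster <- cumsum(c(1L, as.integer(lo[-1] > cummax(hi[-np]))))
  mz_all <- numeric(0); int_all <- numeric(0)
  for (cl in unique(cluster)) {
    idx <- which(cluster == cl)
    step <- fwhm_from_sigma(peaks$sigma[idx[1]]) / points_per_fwhm
    g_lo <- min(lo[idx]); g_hi <- max(hi[idx])
    phase <- stats::runif(1, 0, step)
    grid <- seq(g_lo + phase, g_hi, by = step)
    if (!length(grid)) next
    model <- rep(0, length(grid))
    for (j in idx)
      model <- model + peaks$height[j] *
        exp(-(grid - peaks$x0[j])^2 / (2 * peaks$sigma[j]^2))
    obs <- if (noise_cv > 0)
      model * exp(stats::rnorm(length(grid), 0, noise_cv)) else model
    obs[obs < intensity_floor] <- 0
    nz <- obs > 0
    if (!any(nz)) next
    # keep nonzero points plus the zero points adjacent to them
    keep <- nz | c(nz[-1], FALSE) | c(FALSE, nz[-length(nz)])
    # ensure explicit flanking zeros even at the grid edge
    gmz <- grid[keep]; gint <- obs[keep]
    if (gint[1] > 0) { gmz <- c(gmz[1] - step, gmz); gint <- c(0, gint) }
    n <- length(gint)
    if (gint[n] > 0) { gmz <- c(gmz, gmz[n] + step); gint <- c(gint, 0) }
    mz_all <- c(mz_all, gmz); int_all <- c(int_all, gint)
  }
  # clusters are disjoint but flanking zeros may collide; enforce order
  if (length(mz_all) > 1) {
    keep <- c(TRUE, diff(mz_all) > 0)
    mz_all <- mz_all[keep]; int_all <- int_all[keep]
  }
  structure(
    list(peaks = peaks,
         spectrum = new_spectrum(mz_all, int_all, scan_id = scan_id,
                                 ms_level = 1L,
                                 retention_time = retention_time,
                                 polarity = "positive",
                                 scan_index = scan_index),
         noise_cv = noise_cv, points_per_fwhm = points_per_fwhm,
         window_sigma = window_sigma, intensity_floor = intensity_floor,
         r_ref = r_ref, exponent = exponent, seed = seed),
    class = "SyntheticTruth")
}

#' Overlap-versus-DQS simulation
#'
#' Quantifies how the Data Quality Score degrades when two peaks approach
#' each other. For each separation `s` (in multiples of the peak width
#' sigma), `n_rep` pairs of equal-height Gaussians centered `s * sigma`
#' apart are generated, run through the full pipeline (isolate, fit,
#' score), and the DQS values of all resulting centroids are summarized.
#' Down to separations around 2 sigma the summed profile still has a
#' valley and is split; below that a single merged profile is fitted,
#' which the score penalizes.
#'
#' @param separations Center separations in multiples of sigma
#'   (default 6 down to 1.5 in steps of 0.5).
#' @param n_rep Replicate pairs per separation (default 200).
#' @param noise_cv Multiplicative noise level (default 0.01).
#' @param seed Integer seed for the whole experiment.
#' @param mz_center Midpoint of each pair (default 200).
#' @param height Peak height (default 1e6).
#' @param ... Further arguments passed to [generate_spectrum()].
#' @return Data frame with one row per separation: `separation`,
#'   `mean_dqs`, `sd_dqs`, `n_centroids`, `mean_centroids_per_pair`.
#' @export
overlap_experiment <- function(separations = seq(6, 1.5, by = -0.5),
                               n_rep = 200, noise_cv = 0.01, seed = 1,
                               mz_center = 200, height = 1e6, ...) {
  stopifnot(all(separations > 0), n_rep >= 1)
  set.seed(seed)
  sigma <- orbitrap_width_model(mz_center)
  rows <- lapply(separations, function(s) {
    dqs <- numeric(0)
    for (r in seq_len(n_rep)) {
      pk <- data.frame(
        x0 = mz_center + c(-0.5, 0.5) * s * sigma,
        sigma = sigma, height = height)
      tr <- generate_spectrum(peaks = pk, noise_cv = noise_cv,
                              seed = NULL, ...)
      cent <- centroid_spectrum(tr$spectrum)$centroids
      dqs <- c(dqs, cent$dqs)
    }
    data.frame(separation = s,
               mean_dqs = mean(dqs),
               sd_dqs = stats::sd(dqs),
               n_centroids = length(dqs),
               mean_centroids_per_pair = length(dqs) / n_rep)
  })
  do.call(rbind, rows)
}
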