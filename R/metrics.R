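# Derived quantities: FWHM, mass resolution, mass accuracy, the
# resolution-vs-m/z power law, and cross-scan centroid grouping.

.FWHM_CONST <- 2 * sqrt(2 * log(2))

#' Full width at half maximum of a Gaussian peak
#'
#' For a Gaussian the FWHM and the standard deviation are interchangeable:
#' `FWHM = 2 sqrt(2 ln 2) * sigma`.
#'
#' @param sigma Peak standard deviation(s) in m/z units, > 0.
#' @return FWHM in m/z units.
#' @export
fwhm_from_sigma <- function(sigma) {
  if (any(sigma <= 0)) stop("sigma must be > 0")
  .FWHM_CONST * sigma
}

#' @rdname fwhm_from_sigma
#' @param fwhm FWHM value(s) in m/z units, > 0.
#' @export
sigma_from_fwhm <- function(fwhm) {
  if (any(fwhm <= 0)) stop("fwhm must be > 0")
  fwhm / .FWHM_CONST
}

#' Mass resolution R = m / delta-m
#'
#' @param mz Peak position(s) in m/z units.
#' @param fwhm Peak width(s) as FWHM in m/z units, > 0.
#' @return Dimensionless resolution.
#' @export
mass_resolution <- function(mz, fwhm) {
  if (any(fwhm <= 0)) stop("fwhm must be > 0")
  mz / fwhm
}

#' Signed mass accuracy in parts per million
#'
#' `(measured - exact) / exact * 1e6`.
#'
#' @param measured Measured m/z value(s).
#' @param exact Exact (theoretical) m/z value(s), > 0.
#' @return Signed ppm error(s).
#' @export
mass_accuracy_ppm <- function(measured, exact) {
  if (any(exact <= 0)) stop("exact mass must be > 0")
  (measured - exact) / exact * 1e6
}

#' Fit the resolution--m/z power law R = a * m^b
#'
#' Orbitrap resolving power falls off with mass approximately as
#' `R ~ m^-0.5`. This fits the power law to per-peak (m/z, resolution)
#' pairs by iterative non-linear least squares, initialized from the
#' log--log linear fit.
#'
#' @param mz Numeric vector of peak positions (> 0), length >= 3.
#' @param resolution Numeric vector of per-peak resolutions (> 0).
#' @return A `ResolutionFit`: list with coefficients `a`, `b`, standard
#'   errors `se_a`, `se_b`, `n`, and the underlying `nls` fit object.
#' @examples
#' mz <- seq(100, 1000, length.out = 10)
#' fit <- fit_resolution_power_law(mz, 70000 * (200 / mz)^0.5)
#' fit$b  # -0.5
#' @export
fit_resolution_power_law <- function(mz, resolution) {
  if (length(mz) != length(resolution)) stop("length mismatch")
  if (length(mz) < 3) stop("need at least 3 points")
  if (any(mz <= 0) || any(resolution <= 0)) stop("values must be positive")
  if (diff(range(mz)) == 0) stop("degenerate input: all m/z equal")
  init <- stats::lm(log(resolution) ~ log(mz))
  start <- list(a = exp(stats::coef(init)[[1]]), b = stats::coef(init)[[2]])
  df <- data.frame(mz = mz, resolution = resolution)
  fit <- minpack.lm::nlsLM(resolution ~ a * mz^b, data = df, start = start,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  s <- summary(fit)$coefficients
  structure(
    list(a = s["a", "Estimate"], b = s["b", "Estimate"],
         se_a = s["a", "Std. Error"], se_b = s["b", "Std. Error"],
         n = length(mz), fit = fit),
    class = "ResolutionFit")
}

#' @export
print.ResolutionFit <- function(x, ...) {
  cat(sprintf("Power law R = a * m^b: a = %.6g (se %.3g), b = %.6g (se %.3g), n = %d\n",
              x$a, x$se_a, x$b, x$se_b, x$n))
  cat(sprintf("  R(200) = %.1f\n", x$a * 200^x$b))
  invisible(x)
}

#' Group centroids across consecutive scans for m/z precision
#'
#' Chains centroids of the same ion species over successive scans of one
#' run, the construction used to measure m/z precision (relative standard
#' deviation in ppm) per group. A centroid joins an open group when its
#' m/z lies within `ppm_tol` of the group's running mean and the number of
#' skipped scans since the group's last member is at most `max_gap`.
#' Groups smaller than `min_size` are discarded.
#'
#' @param records Centroid data frame (needs `scan_index` and
#'   `mz_centroid`; [centroid_spectra()] output qualifies).
#' @param ppm_tol Membership tolerance in ppm against the running mean
#'   (default 3, a typical extracted-ion-chromatogram mass window).
#' @param max_gap Maximum number of consecutive missing scans inside a
#'   group (default 2).
#' @param min_size Minimum surviving group size (default 10).
#' @return A list of `CentroidGroup` objects: `members` (data frame in
#'   scan order), `mean_mz`, `rsd_ppm`, `n`.
#' @export
group_centroids <- function(records, ppm_tol = 3, max_gap = 2, min_size = 10) {
  records <- as.data.frame(records)
  if (!nrow(records)) return(list())
  if (!"scan_index" %in% names(records))
    stop("records must carry a scan_index column")
  records <- records[order(records$scan_index, records$mz_centroid), ,
                     drop = FALSE]
  open <- list()    # each: list(rows, sum_mz, n, last_scan)
  closed <- list()
  for (i in seq_len(nrow(records))) {
    scan <- records$scan_index[i]
    mz <- records$mz_centroid[i]
    if (length(open)) {
      expired <- vapply(open, function(g)
        scan - g$last_scan - 1L > max_gap, logical(1))
      closed <- c(closed, open[expired])
      open <- open[!expired]
    }
    best <- 0L; best_ppm <- Inf
    for (k in seq_along(open)) {
      g <- open[[k]]
      if (scan == g$last_scan) next   # one member per scan per group
      mean_mz <- g$sum_mz / g$n
      d <- abs(mz - mean_mz) / mean_mz * 1e6
      if (d <= ppm_tol && d < best_ppm) { best <- k; best_ppm <- d }
    }
    if (best) {
      open[[best]]$rows <- c(open[[best]]$rows, i)
      open[[best]]$sum_mz <- open[[best]]$sum_mz + mz
      open[[best]]$n <- open[[best]]$n + 1L
      open[[best]]$last_scan <- scan
    } else {
      open <- c(open, list(list(rows = i, sum_mz = mz, n = 1L,
                                last_scan = scan)))
    }
  }
  closed <- c(closed, open)
  keep <- Filter(function(g) g$n >= min_size, closed)
  lapply(keep, function(g) {
    members <- records[g$rows, , drop = FALSE]
    mean_mz <- mean(members$mz_centroid)
    rsd <- if (g$n > 1) stats::sd(members$mz_centroid) / mean_mz * 1e6 else 0
    structure(list(members = members, mean_mz = mean_mz,
                   rsd_ppm = rsd, n = g$n),
              class = "CentroidGroup")
  })
}

#' @export
print.CentroidGroup <- function(x, ...) {
  cat(sprintf("CentroidGroup: n = %d, mean m/z = %.6f, RSD = %.3f ppm\n",
              x$n, x$mean_mz, x$rsd_ppm))
  invisible(x)
}
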