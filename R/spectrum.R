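#' Construct a profile-mode spectrum
#'
#' Container for one profile-mode scan: parallel m/z and intensity arrays
#' plus scan metadata. Zero intensities are meaningful (they delimit peak
#' profiles) and must not be stripped.
#'
#' @param mz Numeric vector of m/z values, strictly increasing.
#' @param intensity Numeric vector of intensities, same length as `mz`,
#'   all values >= 0.
#' @param scan_id Source-native scan identifier (character scalar).
#' @param ms_level Integer MS level (>= 1).
#' @param retention_time Retention time in seconds, or `NA` for
#'   acquisitions without a chromatographic domain (direct infusion).
#' @param polarity One of `"positive"`, `"negative"`, `"unknown"`.
#' @param scan_index Integer position of the scan in its run (file order);
#'   used for output ordering and cross-scan grouping.
#'
#' @return An object of class `"Spectrum"`: a list with the above fields.
#' @examples
#' sp <- new_spectrum(mz = c(199.998, 200.000, 200.002, 200.004),
#'                    intensity = c(0, 5e5, 1e6, 0))
#' sp$ms_level
#' @export
new_spectrum <- function(mz, intensity, scan_id = "scan=1", ms_level = 1L,
                         retention_time = NA_real_, polarity = "unknown",
                         scan_index = 1L) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity))
    stop("mz and intensity must have the same length")
  if (length(mz) > 1L && any(diff(mz) <= 0))
    stop("mz values must be strictly increasing (scan ", scan_id, ")")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop("intensities must be finite and non-negative (scan ", scan_id, ")")
  polarity <- match.arg(polarity, c("positive", "negative", "unknown"))
  structure(
    list(scan_id = as.character(scan_id),
         ms_level = as.integer(ms_level),
         retention_time = as.numeric(retention_time),
         mz = mz,
         intensity = intensity,
         polarity = polarity,
         scan_index = as.integer(scan_index)),
    class = "Spectrum")
}

#' @export
print.Spectrum <- function(x, ...) {
  cat("Spectrum", x$scan_id,
      sprintf("(MS%d, %s", x$ms_level, x$polarity),
      if (is.finite(x$retention_time))
        sprintf("rt=%.3fs)", x$retention_time) else "rt=NA)",
      "\n")
  cat("  ", length(x$mz), "points, m/z",
      if (length(x$mz)) sprintf("%.4f..%.4f", min(x$mz), max(x$mz)) else "-",
      ",", sum(x$intensity == 0), "zero intensities\n")
  invisible(x)
}
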