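# Peak-profile isolation: zero-delimited runs plus valley splitting of
# overlapping profiles.

#' Isolate peak profiles within one spectrum
#'
#' Splits a profile spectrum into candidate peak profiles. Resolved
#' profiles are delimited by the zero intensities surrounding them, which
#' act as predefined peak boundaries. Overlapping profiles inside one
#' nonzero run are separated at valley points (strict local intensity
#' minima); the valley point itself is assigned to both adjacent profiles,
#' and the shared edges are flagged.
#'
#' @param spectrum A `Spectrum` object.
#' @param gap_factor Numeric; within a nonzero run, an m/z step larger than
#'   `gap_factor` times the run's median step is treated as an implicit
#'   zero boundary (vendors may omit rather than store zero points). The
#'   default 4 is inert on fully zero-padded data. `Inf` disables the rule.
#'
#' @return A list of `PeakProfile` objects, left to right. Each carries the
#'   m/z and intensity slices (all intensities > 0), the 1-based inclusive
#'   index range `start:end` into the spectrum arrays, `split_left` /
#'   `split_right` flags for shared valley edges, and the scan metadata.
#'
#' @details A plateau (a flat run of equal minimal intensities between two
#'   higher neighbours) is treated as a single valley located at its
#'   leftmost index, keeping the assignment rule deterministic. Only exact
#'   zeros are boundaries; no epsilon threshold is applied.
#' @examples
#' sp <- new_spectrum(mz = 1:7 / 1000 + 100,
#'                    intensity = c(0, 1, 5, 2, 6, 1, 0))
#' length(isolate_profiles(sp))  # two profiles sharing the valley point
#' @export
isolate_profiles <- function(spectrum, gap_factor = 4) {
  stopifnot(inherits(spectrum, "Spectrum"))
  int <- spectrum$intensity
  n <- length(int)
  if (!n || all(int == 0)) return(list())
  nz <- int > 0
  run_start <- which(nz & !c(FALSE, nz[-n]))
  run_end <- which(nz & !c(nz[-1], FALSE))
  profiles <- list()
  for (r in seq_along(run_start)) {
    segs <- .split_run_gaps(spectrum$mz, run_start[r], run_end[r], gap_factor)
    for (s in seq_len(nrow(segs))) {
      profiles <- c(profiles,
                    .split_run_valleys(spectrum, segs[s, 1], segs[s, 2]))
    }
  }
  profiles
}

# Break a run [a, b] where the m/z grid has a gap > gap_factor x the run's
# median step. Returns a matrix of (start, end) rows.
.split_run_gaps <- function(mz, a, b, gap_factor) {
  if (b - a < 1L || !is.finite(gap_factor))
    return(matrix(c(a, b), ncol = 2))
  d <- diff(mz[a:b])
  breaks <- which(d > gap_factor * stats::median(d))
  if (!length(breaks)) return(matrix(c(a, b), ncol = 2))
  starts <- c(a, a + breaks)
  ends <- c(a + breaks - 1L, b)
  cbind(starts, ends)
}

# Valley-split one gap-free run [a, b]; valley points are shared.
.split_run_valleys <- function(spectrum, a, b) {
  v <- spectrum$intensity[a:b]
  len <- length(v)
  valleys <- integer(0)
  i <- 2L
  while (i <= len - 1L) {
    if (v[i] < v[i - 1L]) {
      j <- i
      while (j < len && v[j + 1L] == v[i]) j <- j + 1L
      if (j < len && v[j + 1L] > v[i]) valleys <- c(valleys, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  bounds_lo <- c(a, a + valleys - 1L)
  bounds_hi <- c(a + valleys - 1L, b)
  lapply(seq_along(bounds_lo), function(k) {
    structure(
      list(mz = spectrum$mz[bounds_lo[k]:bounds_hi[k]],
           intensity = spectrum$intensity[bounds_lo[k]:bounds_hi[k]],
           start = bounds_lo[k], end = bounds_hi[k],
           split_left = k > 1L,
           split_right = k < length(bounds_lo),
           scan_id = spectrum$scan_id,
           scan_index = spectrum$scan_index,
           ms_level = spectrum$ms_level,
           retention_time = spectrum$retention_time),
      class = "PeakProfile")
  })
}

#' @export
print.PeakProfile <- function(x, ...) {
  cat(sprintf("PeakProfile [%d..%d] of %s: %d points, apex %.6g @ m/z %.6f%s\n",
              x$start, x$end, x$scan_id, length(x$mz), max(x$intensity),
              x$mz[which.max(x$intensity)],
              if (x$split_left || x$split_right) " (valley-split)" else ""))
  invisible(x)
}
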