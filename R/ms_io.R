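# I/O layer: open-format spectrum reading (mzML/mzXML via mzR) and the
# canonical 13-column centroid CSV.

.CENTROID_COLUMNS <- c("scan_id", "retention_time", "ms_level", "mz_centroid",
                       "height", "area", "sigma", "fwhm", "dqs", "category",
                       "n_points", "nrmse", "apex_inside")

#' Read profile-mode spectra from mzML or mzXML
#'
#' Reads every spectrum of an open-format raw file into [new_spectrum()]
#' containers, preserving zero-intensity points (they are consumed later as
#' peak-profile boundaries). The file dialect (mzML 1.1 or mzXML 3.x) is
#' detected from the file content by the proteowizard-based backend, not
#' from the extension alone.
#'
#' @param path Path to an mzML or mzXML file.
#' @param ms_level_filter Optional integer vector; only spectra whose MS
#'   level is in this set are returned. `NULL` (default) keeps all levels.
#'
#' @return A list of `Spectrum` objects in file order.
#'
#' @details A spectrum containing no zero intensities at all is likely
#'   already centroided; it is still returned, with a warning naming the
#'   scan. A spectrum whose m/z values are not strictly increasing is a
#'   fatal format error.
#' @export
read_profile_spectra <- function(path, ms_level_filter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle), add = TRUE)
  hdr <- mzR::header(handle)
  out <- vector("list", nrow(hdr))
  kept <- 0L
  for (i in seq_len(nrow(hdr))) {
    lvl <- hdr$msLevel[i]
    if (!is.null(ms_level_filter) && !(lvl %in% ms_level_filter)) next
    pk <- mzR::peaks(handle, i)
    scan_id <- if (!is.null(hdr$spectrumId) && nzchar(hdr$spectrumId[i]))
      hdr$spectrumId[i] else paste0("scan=", hdr$acquisitionNum[i])
    mzv <- pk[, 1]
    if (length(mzv) > 1L && any(diff(mzv) <= 0))
      stop("m/z values not strictly increasing in scan ", scan_id)
    pol <- hdr$polarity[i]
    polarity <- if (is.na(pol)) "unknown"
      else if (pol > 0) "positive" else if (pol == 0) "negative" else "unknown"
    rt <- hdr$retentionTime[i]
    sp <- new_spectrum(mz = mzv, intensity = pk[, 2], scan_id = scan_id,
                       ms_level = lvl,
                       retention_time = if (is.null(rt)) NA_real_ else rt,
                       polarity = polarity, scan_index = i)
    if (length(sp$intensity) && all(sp$intensity > 0))
      warning("scan ", scan_id, " contains no zero intensities; ",
              "it may already be centroided", call. = FALSE)
    kept <- kept + 1L
    out[[kept]] <- sp
  }
  out[seq_len(kept)]
}

#' Write the centroid table to CSV
#'
#' Writes one row per accepted peak profile with the fixed 13-column schema
#' `scan_id, retention_time, ms_level, mz_centroid, height, area, sigma,
#' fwhm, dqs, category, n_points, nrmse, apex_inside`, sorted by scan order
#' and then centroid m/z. Floating-point fields carry 12 significant digits
#' so that a write/read cycle reproduces the values; a missing retention
#' time is written as an empty field, never as 0.
#'
#' @param records Centroid data frame as produced by [centroid_spectra()];
#'   may be empty. An internal `scan_index` column, if present, supplies the
#'   scan order (otherwise first appearance of `scan_id` is used).
#' @param path Output CSV path.
#' @return Invisibly, the number of rows written.
#' @seealso [read_centroid_table()] for the inverse.
#' @export
write_centroid_table <- function(records, path) {
  records <- as.data.frame(records)
  if (nrow(records)) {
    ord_key <- if ("scan_index" %in% names(records)) records$scan_index
      else match(records$scan_id, unique(records$scan_id))
    records <- records[order(ord_key, records$mz_centroid), , drop = FALSE]
  }
  num <- function(x) ifelse(is.na(x), "", sprintf("%.12g", x))
  cols <- if (nrow(records)) data.frame(
    scan_id = as.character(records$scan_id),
    retention_time = num(records$retention_time),
    ms_level = as.character(records$ms_level),
    mz_centroid = num(records$mz_centroid),
    height = num(records$height),
    area = num(records$area),
    sigma = num(records$sigma),
    fwhm = num(records$fwhm),
    dqs = num(records$dqs),
    category = as.character(records$category),
    n_points = as.character(records$n_points),
    nrmse = num(records$nrmse),
    apex_inside = ifelse(records$apex_inside, "TRUE", "FALSE"),
    stringsAsFactors = FALSE)
  else as.data.frame(setNames(rep(list(character(0)), 13), .CENTROID_COLUMNS))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con), add = TRUE)
  utils::write.csv(cols, con, row.names = FALSE, quote = c(1L, 10L))
  invisible(nrow(cols))
}

#' Read a centroid table written by [write_centroid_table()]
#'
#' @param path Path to a centroid CSV.
#' @return A data frame with the 13 canonical columns and proper types.
#' @export
read_centroid_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(scan_id = "character",
                                       category = "character"))
  if (!identical(names(df), .CENTROID_COLUMNS))
    stop("not a centroid table: unexpected columns in ", path)
  df$apex_inside <- as.logical(df$apex_inside)
  df
}

#' Write spectra to a profile-mode mzML file
#'
#' Serializes `Spectrum` objects (typically from [generate_spectrum()]) as
#' profile-mode mzML, so that the full file-based pipeline can be exercised
#' end to end. Intensities and m/z are encoded in 64-bit precision.
#'
#' @param spectra A list of `Spectrum` objects (or a single one).
#' @param path Output path ending in `.mzML`.
#' @return Invisibly, `path`.
#' @export
write_profile_mzml <- function(spectra, path) {
  if (inherits(spectra, "Spectrum")) spectra <- list(spectra)
  n <- length(spectra)
  if (!n) stop("no spectra to write")
  pks <- lapply(spectra, function(s) cbind(mz = s$mz, intensity = s$intensity))
  pol_code <- function(p) switch(p, positive = 1L, negative = 0L, -1L)
  hdr <- data.frame(
    seqNum = seq_len(n),
    acquisitionNum = seq_len(n),
    msLevel = vapply(spectra, function(s) s$ms_level, integer(1)),
    polarity = vapply(spectra, function(s) pol_code(s$polarity), integer(1)),
    peaksCount = vapply(pks, nrow, integer(1)),
    totIonCurrent = vapply(spectra, function(s) sum(s$intensity), numeric(1)),
    retentionTime = vapply(spectra, function(s)
      if (is.finite(s$retention_time)) s$retention_time else 0, numeric(1)),
    basePeakMZ = vapply(spectra, function(s)
      if (length(s$mz)) s$mz[which.max(s$intensity)] else 0, numeric(1)),
    basePeakIntensity = vapply(spectra, function(s)
      if (length(s$intensity)) max(s$intensity) else 0, numeric(1)),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(spectra, function(s)
      if (length(s$mz)) min(s$mz) else 0, numeric(1)),
    highMZ = vapply(spectra, function(s)
      if (length(s$mz)) max(s$mz) else 0, numeric(1)),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = vapply(spectra, function(s) s$scan_id, character(1)),
    centroided = FALSE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_,
    stringsAsFactors = FALSE)
  mzR::writeMSData(pks, file = path, header = hdr)
  invisible(path)
}
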