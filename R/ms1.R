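# In-memory MS1 map and mzML I/O.

#' Construct an in-memory MS1 map
#'
#' An MS1 map is the minimal container the extraction code needs: a strictly
#' increasing retention-time grid (minutes) and one centroided peak list
#' (two-column matrix: m/z, intensity; sorted by m/z) per scan.
#'
#' @param rt Numeric vector of retention times in minutes, strictly
#'   increasing.
#' @param peaks List of numeric matrices with columns `mz`, `intensity`.
#' @param run_id Character scalar naming the run.
#' @return An `ms1_map` object.
#' @export
ms1_map <- function(rt, peaks, run_id = "run") {
  stopifnot(is.numeric(rt), length(rt) == length(peaks))
  if (length(rt) > 1L && any(diff(rt) <= 0))
    stop("retention times must be strictly increasing")
  peaks <- lapply(peaks, function(p) {
    p <- matrix(as.numeric(p), ncol = 2,
                dimnames = list(NULL, c("mz", "intensity")))
    if (any(p[, 2] < 0)) stop("intensities must be nonnegative")
    p[order(p[, 1]), , drop = FALSE]
  })
  structure(list(rt = as.numeric(rt), peaks = peaks,
                 run_id = as.character(run_id)),
            class = "ms1_map")
}

#' @export
print.ms1_map <- function(x, ...) {
  cat(sprintf("<ms1_map> run '%s': %d scans, RT %.2f-%.2f min, %d peaks\n",
              x$run_id, length(x$rt),
              if (length(x$rt)) min(x$rt) else NA, if (length(x$rt)) max(x$rt) else NA,
              sum(vapply(x$peaks, nrow, 0L))))
  invisible(x)
}

#' Read MS1 scans from an mzML/mzXML file
#'
#' Reads only MS level 1 scans. Input must be centroided: profile-mode
#' spectra are rejected. Scans whose centroided flag is missing are accepted
#' (many converters leave it unset) but a warning is emitted.
#'
#' @param path Path to an mzML or mzXML file.
#' @param run_id Run identifier; defaults to the file name without extension.
#' @return An [ms1_map()].
#' @export
read_ms1 <- function(path, run_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(run_id)) run_id <- sub("\\.[^.]+$", "", basename(path))
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle))
  hdr <- mzR::header(handle)
  ms1 <- which(hdr$msLevel == 1L)
  if (length(ms1) == 0L) stop("no MS1 scans in ", path)
  cent <- hdr$centroided[ms1]
  if (any(!is.na(cent) & !cent))
    stop("profile-mode MS1 spectra found in ", path,
         "; centroided input is required")
  if (anyNA(cent))
    warning("centroided flag missing for some scans in ", basename(path),
            "; assuming centroided input")
  pk <- mzR::peaks(handle, ms1)
  if (is.matrix(pk)) pk <- list(pk)
  ms1_map(rt = hdr$retentionTime[ms1] / 60, peaks = pk, run_id = run_id)
}

#' Write an MS1 map to an mzML file
#'
#' @param map An [ms1_map()].
#' @param path Output path (".mzML").
#' @return `path`, invisibly.
#' @export
write_ms1 <- function(map, path) {
  stopifnot(inherits(map, "ms1_map"))
  n <- length(map$rt)
  npk <- vapply(map$peaks, nrow, 0L)
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = 1L, peaksCount = npk,
    totIonCurrent = vapply(map$peaks, function(p) sum(p[, 2]), 0),
    retentionTime = map$rt * 60,
    basePeakMZ = vapply(map$peaks, function(p)
      if (nrow(p)) p[which.max(p[, 2]), 1] else 0, 0),
    basePeakIntensity = vapply(map$peaks, function(p)
      if (nrow(p)) max(p[, 2]) else 0, 0),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(map$peaks, function(p) if (nrow(p)) min(p[, 1]) else 0, 0),
    highMZ = vapply(map$peaks, function(p) if (nrow(p)) max(p[, 1]) else 0, 0),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)), centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_,
    stringsAsFactors = FALSE)
  mzR::writeMSData(object = map$peaks, file = path, header = hdr,
                   outformat = "mzml")
  invisible(path)
}
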