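# Per-isotopologue trace extraction and cosine linking of isotopologue
# clusters.

# Extract one intensity per scan for each target m/z from a sorted peak
# matrix list. When several peaks fall inside the ppm window the most
# intense one is taken (standard XIC practice; deterministic).
.extract_matrix <- function(peaks, targets, ppm_tol) {
  out <- matrix(0, nrow = length(peaks), ncol = length(targets))
  lo_mz <- targets * (1 - ppm_tol * 1e-6)
  hi_mz <- targets * (1 + ppm_tol * 1e-6)
  for (s in seq_along(peaks)) {
    p <- peaks[[s]]
    if (nrow(p) == 0L) next
    mz <- p[, 1]
    lo <- findInterval(lo_mz, mz, left.open = TRUE)   # last peak < lo bound
    hi <- findInterval(hi_mz, mz)                     # last peak <= hi bound
    for (j in seq_along(targets)) {
      if (hi[j] > lo[j])
        out[s, j] <- max(p[(lo[j] + 1L):hi[j], 2])
    }
  }
  out
}

#' Extract isotopologue traces for a labeled peptide pair
#'
#' Subsets the MS1 map around the predicted retention time and pulls, for
#' every isotopologue of the light and heavy species, the most intense peak
#' within `ppm_tol` of its predicted m/z in each scan (0 where no peak
#' matches).
#'
#' @param ms1 An [ms1_map()].
#' @param geometry A `pair_geometry` from [pair_positions()].
#' @param rt_center Predicted retention time, minutes.
#' @param rt_halfwidth Extraction half-window, minutes (default 1.0).
#' @param ppm_tol Mass tolerance in ppm (default 10).
#' @return A `trace_set`: list with `rt` (scan times in window), `light` and
#'   `heavy` intensity matrices (scans x isotopologues), the inputs used,
#'   and `valid` (FALSE when the window contains no scans).
#' @export
extract_traces <- function(ms1, geometry, rt_center, rt_halfwidth = 1.0,
                           ppm_tol = 10) {
  stopifnot(inherits(ms1, "ms1_map"), inherits(geometry, "pair_geometry"))
  if (ppm_tol <= 0) stop("ppm_tol must be positive")
  sel <- which(ms1$rt >= rt_center - rt_halfwidth &
               ms1$rt <= rt_center + rt_halfwidth)
  if (length(sel) == 0L) {
    return(structure(list(rt = numeric(0),
                          light = matrix(0, 0, length(geometry$light_mz)),
                          heavy = matrix(0, 0, length(geometry$heavy_mz)),
                          geometry = geometry, ppm_tol = ppm_tol,
                          rt_center = rt_center, valid = FALSE),
                     class = "trace_set"))
  }
  pk <- ms1$peaks[sel]
  structure(list(rt = ms1$rt[sel],
                 light = .extract_matrix(pk, geometry$light_mz, ppm_tol),
                 heavy = .extract_matrix(pk, geometry$heavy_mz, ppm_tol),
                 geometry = geometry, ppm_tol = ppm_tol,
                 rt_center = rt_center, valid = TRUE),
            class = "trace_set")
}

#' Cosine similarity between two isotopologue traces
#'
#' Traces must lie on the same scan grid. Returns 0 when either trace is
#' all-zero.
#'
#' @param a,b Numeric per-scan intensity vectors.
#' @return Similarity in \[0, 1\].
#' @export
trace_cosine <- function(a, b) {
  if (length(a) != length(b)) stop("mismatched scan grids")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  min(1, max(0, sum(a * b) / (na * nb)))
}

#' Link consecutive isotopologue traces into a cluster
#'
#' Consecutive isotopologues are connected only if they share a cosine
#' similarity at or above `threshold` (default 0.6, inclusive). The cluster
#' is the maximal prefix of isotopologue indices, starting at the
#' monoisotopic trace, in which every adjacent pair is connected; traces
#' after the first failing link are discarded.
#'
#' @param traces Matrix of per-scan intensities, one column per isotopologue
#'   index starting at 0.
#' @param threshold Minimum adjacent cosine (default 0.6).
#' @return A `feature_cluster`: list with `kept` (0-based indices retained)
#'   and `cosines` (adjacent similarities over the kept prefix).
#' @export
link_cluster <- function(traces, threshold = 0.6) {
  traces <- as.matrix(traces)
  ncols <- ncol(traces)
  if (ncols == 0L)
    return(structure(list(kept = integer(0), cosines = numeric(0)),
                     class = "feature_cluster"))
  cosines <- numeric(0)
  kept_n <- 1L
  for (j in seq_len(ncols - 1L)) {
    cs <- trace_cosine(traces[, j], traces[, j + 1L])
    if (cs >= threshold) {
      cosines <- c(cosines, cs)
      kept_n <- j + 1L
    } else break
  }
  structure(list(kept = 0:(kept_n - 1L), cosines = cosines),
            class = "feature_cluster")
}
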