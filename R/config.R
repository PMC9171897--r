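# Pipeline configuration: thresholds, tolerances and channel assignment.

#' Pipeline configuration
#'
#' Collects every tunable of the workflow, pinned by default to the assay's
#' quality cutoffs: adjacent-isotopologue cosine 0.6, slope-regression
#' R-squared 0.8, titration-fit NRMSE 0.2, 7 valid values out of 12 per age
#' group, and significance at q <= 0.01.
#'
#' @param cosine_threshold Minimum adjacent-isotopologue cosine similarity.
#' @param r2_threshold Minimum coefficient of determination of the
#'   light-on-heavy slope regression.
#' @param nrmse_threshold Maximum normalized RMSE of the titration fit.
#' @param min_valid Minimum valid per-run measurements per age group.
#' @param q_threshold q-value / adjusted-p significance cutoff.
#' @param ppm_tol Extraction mass tolerance, ppm.
#' @param rt_halfwidth Extraction retention-time half-window, minutes.
#' @param K Maximum isotopologue index per species.
#' @param light_channel 0-based light-species isotopologue indices summed
#'   into the light channel (default 0:1 — the only positions free of heavy
#'   spillover under the +2 label shift).
#' @param heavy_channel 0-based heavy-species isotopologue indices summed
#'   into the heavy channel (default 0:K).
#' @param max_components Maximum Gaussian components in the elution fit.
#' @param min_points Minimum scans with heavy signal for the slope fit.
#' @param drop_cysteine Remove cysteine-containing peptides (their oxidation
#'   is chemically reversible and not quantifiable by the blocking assay).
#' @param nrmse_normalizer `"mean"` (default) or `"range"` of observed MOS.
#' @param clip_measurements Clip per-run MOS values to \[0, 1\] before the
#'   titration fit (default FALSE: the in vivo parameter is bounded instead).
#' @param seed Integer seed recorded in outputs.
#' @return A `mos_config` list.
#' @export
mos_config <- function(cosine_threshold = 0.6,
                       r2_threshold = 0.8,
                       nrmse_threshold = 0.2,
                       min_valid = 7L,
                       q_threshold = 0.01,
                       ppm_tol = 10,
                       rt_halfwidth = 1.0,
                       K = 6L,
                       light_channel = 0:1,
                       heavy_channel = NULL,
                       max_components = 3L,
                       min_points = 5L,
                       drop_cysteine = TRUE,
                       nrmse_normalizer = c("mean", "range"),
                       clip_measurements = FALSE,
                       seed = 1L) {
  if (is.null(heavy_channel)) heavy_channel <- 0:K
  cfg <- list(cosine_threshold = cosine_threshold,
              r2_threshold = r2_threshold,
              nrmse_threshold = nrmse_threshold,
              min_valid = as.integer(min_valid),
              q_threshold = q_threshold,
              ppm_tol = ppm_tol,
              rt_halfwidth = rt_halfwidth,
              K = as.integer(K),
              light_channel = as.integer(light_channel),
              heavy_channel = as.integer(heavy_channel),
              max_components = as.integer(max_components),
              min_points = as.integer(min_points),
              drop_cysteine = isTRUE(drop_cysteine),
              nrmse_normalizer = match.arg(nrmse_normalizer),
              clip_measurements = isTRUE(clip_measurements),
              seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "mos_config")
}

#' Validate a pipeline configuration
#'
#' @param cfg A configuration list.
#' @return `cfg` invisibly; stops with a message naming the first offending
#'   field otherwise.
#' @export
validate_config <- function(cfg) {
  in01 <- function(x) is.numeric(x) && length(x) == 1L && x >= 0 && x <= 1
  if (!in01(cfg$cosine_threshold)) stop("cosine_threshold must be in [0,1]")
  if (!in01(cfg$r2_threshold)) stop("r2_threshold must be in [0,1]")
  if (!is.numeric(cfg$nrmse_threshold) || cfg$nrmse_threshold <= 0)
    stop("nrmse_threshold must be positive")
  if (cfg$min_valid < 1L) stop("min_valid must be at least 1")
  if (!in01(cfg$q_threshold)) stop("q_threshold must be in [0,1]")
  if (cfg$ppm_tol <= 0) stop("ppm_tol must be positive")
  if (cfg$rt_halfwidth <= 0) stop("rt_halfwidth must be positive")
  if (cfg$K < 3L) stop("K must be at least 3")
  if (length(intersect(cfg$light_channel, cfg$heavy_channel + 2L)) > 0L)
    stop("light and heavy channels overlap on the shared peak axis")
  invisible(cfg)
}

#' Write / read a configuration as JSON
#'
#' Configurations round-trip losslessly so a run can be reproduced from its
#' serialized config.
#'
#' @param cfg A `mos_config`.
#' @param path JSON file path.
#' @return `read_config` returns a `mos_config`.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(mos_config, raw[setdiff(names(raw), character(0))])
  cfg
}
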