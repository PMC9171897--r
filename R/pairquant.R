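# Per-run quantification of one light/heavy peptide pair: extraction,
# elution bounds, cosine linking, channel sums, slope, overlap correction.

.pq_empty <- function() {
  data.frame(peptide = character(0), run = character(0), charge = integer(0),
             slope = numeric(0), r_squared = numeric(0), ratio = numeric(0),
             mos = numeric(0), n_points = integer(0), valid = logical(0),
             reason = character(0), stringsAsFactors = FALSE)
}

.pq_row <- function(peptide, run, charge, slope = NA_real_, r2 = NA_real_,
                    ratio = NA_real_, mos = NA_real_, n_points = 0L,
                    valid = FALSE, reason = NA_character_) {
  data.frame(peptide = peptide, run = run, charge = as.integer(charge),
             slope = slope, r_squared = r2, ratio = ratio, mos = mos,
             n_points = as.integer(n_points), valid = valid, reason = reason,
             stringsAsFactors = FALSE)
}

#' Quantify one labeled peptide pair in one run
#'
#' Runs the full per-pair chain: theoretical envelope and pair geometry,
#' trace extraction around the expected retention time, a Gaussian (mixture)
#' elution fit on the summed trace to delineate the peak, cosine linking of
#' consecutive isotopologues per species, per-scan channel sums over the
#' accepted traces, the light-on-heavy slope regression, envelope-overlap
#' correction, and conversion to MOS. Quality gates (cosine threshold,
#' minimum scans, R-squared) mark the result invalid with a reason rather
#' than erroring.
#'
#' @param ms1 An [ms1_map()].
#' @param sequence Peptide sequence (one Met carrying the sulfoxide label).
#' @param charge Precursor charge state.
#' @param rt Expected retention time, minutes.
#' @param config A [mos_config()].
#' @param modifications Extra modification tokens besides the sulfoxide
#'   label (carbamidomethyl-Cys is added automatically for Cys-containing
#'   sequences, mirroring its status as a fixed modification).
#' @param peptide_id,run_id Identifiers copied into the output row.
#' @return One-row data.frame (a PairQuant record): peptide, run, charge,
#'   slope, r_squared, ratio (corrected L/H), mos, n_points, valid, reason.
#' @export
quantify_pair <- function(ms1, sequence, charge, rt, config = mos_config(),
                          modifications = character(),
                          peptide_id = sequence, run_id = ms1$run_id) {
  mods <- unique(c("mso16", modifications))
  if (grepl("C", sequence, fixed = TRUE) && !"cam_cys" %in% mods)
    mods <- c(mods, "cam_cys")
  comp <- composition_from_sequence(sequence, mods)
  env <- isotope_envelope(comp, K = config$K)
  geom <- pair_positions(env, charge)

  ts <- extract_traces(ms1, geom, rt_center = rt,
                       rt_halfwidth = config$rt_halfwidth,
                       ppm_tol = config$ppm_tol)
  if (!ts$valid)
    return(.pq_row(peptide_id, run_id, charge, reason = "empty RT window"))

  total <- rowSums(ts$light) + rowSums(ts$heavy)
  fit <- fit_elution_profile(ts$rt, total, max_components = config$max_components,
                             rt_predicted = rt, min_points = config$min_points)
  if (!fit$valid)
    return(.pq_row(peptide_id, run_id, charge, reason = fit$reason))

  in_peak <- ts$rt >= fit$bounds[1] & ts$rt <= fit$bounds[2]
  if (sum(in_peak) < config$min_points)
    return(.pq_row(peptide_id, run_id, charge, reason = "insufficient points"))

  light_cl <- link_cluster(ts$light[in_peak, , drop = FALSE],
                           threshold = config$cosine_threshold)
  heavy_cl <- link_cluster(ts$heavy[in_peak, , drop = FALSE],
                           threshold = config$cosine_threshold)

  light_sel <- intersect(config$light_channel, light_cl$kept)
  heavy_sel <- intersect(config$heavy_channel, heavy_cl$kept)
  if (length(heavy_sel) == 0L)
    return(.pq_row(peptide_id, run_id, charge, reason = "no heavy cluster"))
  if (length(light_sel) == 0L) light_sel <- 0L  # monoisotopic always present

  light_sums <- rowSums(ts$light[in_peak, light_sel + 1L, drop = FALSE])
  heavy_sums <- rowSums(ts$heavy[in_peak, heavy_sel + 1L, drop = FALSE])

  est <- estimate_raw_slope(light_sums, heavy_sums,
                            min_points = config$min_points)
  if (!est$valid)
    return(.pq_row(peptide_id, run_id, charge, slope = est$slope,
                   r2 = est$r_squared, n_points = est$n_points,
                   reason = est$reason))

  coeffs <- mixing_coefficients(env, light_channel = light_sel,
                                heavy_channel = heavy_sel + 2L)
  ratio <- correct_overlap(est$slope, coeffs)
  mos <- compute_mos(ratio)

  if (est$r_squared < config$r2_threshold)
    return(.pq_row(peptide_id, run_id, charge, slope = est$slope,
                   r2 = est$r_squared, ratio = ratio, mos = mos,
                   n_points = est$n_points, reason = "R2 below threshold"))

  .pq_row(peptide_id, run_id, charge, slope = est$slope, r2 = est$r_squared,
          ratio = ratio, mos = mos, n_points = est$n_points, valid = TRUE)
}

#' Quantify every evidence target of one run
#'
#' @param ms1 An [ms1_map()].
#' @param evidence Data.frame of extraction targets for this run: columns
#'   `peptide`, `sequence`, `charge`, `rt` (and optionally `modifications`
#'   as ";"-separated tokens).
#' @param config A [mos_config()].
#' @return Data.frame of PairQuant rows, one per target.
#' @export
quantify_run <- function(ms1, evidence, config = mos_config()) {
  rows <- lapply(seq_len(nrow(evidence)), function(i) {
    ev <- evidence[i, ]
    mods <- character(0)
    if (!is.null(ev$modifications) && !is.na(ev$modifications) &&
        nzchar(ev$modifications))
      mods <- setdiff(strsplit(ev$modifications, ";", fixed = TRUE)[[1]],
                      c("mso16", "mso18"))
    quantify_pair(ms1, ev$sequence, ev$charge, ev$rt, config,
                  modifications = mods, peptide_id = ev$peptide,
                  run_id = ms1$run_id)
  })
  do.call(rbind, rows)
}
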