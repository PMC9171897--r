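# Light/heavy ratio estimation: slope regression of channel sums, envelope-
# overlap correction, and conversion to oxidation stoichiometry.

#' Raw light/heavy slope from per-scan channel sums
#'
#' Ordinary least squares of the summed light-channel intensity on the
#' summed heavy-channel intensity across scans, with a free intercept (a
#' constant background is absorbed by the intercept; only the slope is the
#' ratio estimate). The coefficient of determination of the same regression
#' is the quality score. A pure-heavy peptide (light channel identically 0)
#' is a confident measurement: slope 0, R-squared 1.
#'
#' @param light_sums,heavy_sums Per-scan summed channel intensities over the
#'   elution bounds.
#' @param min_points Minimum number of scans with heavy signal (default 5).
#' @return List with `slope`, `r_squared`, `n_points`, `valid`, `reason`.
#' @export
estimate_raw_slope <- function(light_sums, heavy_sums, min_points = 5L) {
  stopifnot(length(light_sums) == length(heavy_sums))
  ok <- heavy_sums > 0
  n <- sum(ok)
  if (n < min_points) {
    # pure-light limit: no heavy signal at all but a real light peak
    if (all(heavy_sums == 0) && sum(light_sums > 0) >= min_points)
      return(list(slope = Inf, r_squared = 1, n_points = sum(light_sums > 0),
                  valid = TRUE, reason = NA_character_))
    return(list(slope = NA_real_, r_squared = NA_real_, n_points = n,
                valid = FALSE, reason = "insufficient points"))
  }
  x <- heavy_sums[ok]; y <- light_sums[ok]
  if (all(y == 0))
    return(list(slope = 0, r_squared = 1, n_points = n,
                valid = TRUE, reason = NA_character_))
  if (stats::var(x) == 0)
    return(list(slope = NA_real_, r_squared = NA_real_, n_points = n,
                valid = FALSE, reason = "degenerate heavy signal"))
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- fit$coefficients[2]
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  list(slope = unname(slope), r_squared = max(0, min(1, r2)), n_points = n,
       valid = TRUE, reason = NA_character_)
}

#' Correct a raw channel ratio for isotope-envelope overlap
#'
#' The observed channels mix the true species signals through the 2x2 model
#' `light_obs = w_LL * L + w_LH * H`, `heavy_obs = w_HL * L + w_HH * H`.
#' With a constant true ratio `rho = L/H` across scans, the regression slope
#' `b` of light on heavy satisfies `b = (w_LL * rho + w_LH) / (w_HL * rho +
#' w_HH)`; inverting gives `rho = (b * w_HH - w_LH) / (w_LL - b * w_HL)`,
#' clamped to `[0, Inf)`.
#'
#' @param raw_slope Nonnegative observed channel slope.
#' @param coeffs `mixing_coefficients` for the peptide's own envelope and
#'   the channel sets actually summed.
#' @return Corrected L/H ratio (nonnegative).
#' @export
correct_overlap <- function(raw_slope, coeffs) {
  stopifnot(inherits(coeffs, "mixing_coefficients"))
  if (is.na(raw_slope)) return(NA_real_)
  if (is.infinite(raw_slope)) return(Inf)  # pure light species
  if (raw_slope < 0) raw_slope <- 0
  wLL <- coeffs$light_channel_weight_L; wLH <- coeffs$light_channel_weight_H
  wHL <- coeffs$heavy_channel_weight_L; wHH <- coeffs$heavy_channel_weight_H
  if (wLL <= 0 && wHL <= 0) stop("singular mixing: no light sensitivity")
  denom <- wLL - raw_slope * wHL
  if (denom <= 0)
    return(Inf)  # slope at/beyond the pure-light limit of the mixing model
  max(0, (raw_slope * wHH - wLH) / denom)
}

#' Oxidation stoichiometry from a corrected light/heavy ratio
#'
#' MOS = r / (1 + r), the light fraction L/(L+H); a ratio of `Inf` (pure
#' light) maps to 1.
#'
#' @param corrected_ratio Nonnegative L/H ratio.
#' @return MOS in \[0, 1\].
#' @export
compute_mos <- function(corrected_ratio) {
  if (is.na(corrected_ratio)) return(NA_real_)
  if (corrected_ratio < 0) stop("corrected ratio must be nonnegative")
  if (is.infinite(corrected_ratio)) return(1)
  corrected_ratio / (1 + corrected_ratio)
}
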