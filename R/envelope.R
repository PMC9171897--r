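# Theoretical isotope envelopes, pair m/z geometry, and channel-mixing
# coefficients for envelope-overlap correction.

# convolve two truncated shift distributions, keeping indices 0..K
.conv_trunc <- function(a, b, K) {
  out <- numeric(K + 1L)
  for (i in seq_along(a)) {
    jmax <- min(length(b), K + 2L - i)
    if (jmax >= 1L)
      out[i:(i + jmax - 1L)] <- out[i:(i + jmax - 1L)] + a[i] * b[seq_len(jmax)]
  }
  out
}

# distribution^n by binary exponentiation, truncated at K
.dist_power <- function(base, n, K) {
  result <- c(1, numeric(K))
  acc <- base
  while (n > 0L) {
    if (n %% 2L == 1L) result <- .conv_trunc(result, acc, K)
    n <- n %/% 2L
    if (n > 0L) acc <- .conv_trunc(acc, acc, K)
  }
  result
}

#' Theoretical aggregated isotope envelope of a composition
#'
#' Computes the relative abundances of the unit-mass-binned isotopologues
#' M+0 .. M+K by convolving the per-element natural isotope distributions
#' ([element_isotopes()]). Aggregated (nominal-shift) isotopologues are used
#' rather than fine isotopic structure, matching what centroided Orbitrap
#' MS1 peak picking at ~120,000 resolution produces for tryptic peptides.
#'
#' @param comp An `elemental_composition`.
#' @param K Maximum isotopologue index (default 6; covers >99.9% of the
#'   envelope mass for tryptic peptides).
#' @return An `isotope_envelope`: list with `abundances` (a0..aK, summing to
#'   at most 1; mass beyond K is truncated), `monoisotopic_mass`, `spacing`
#'   (Da per isotopologue index) and `label`.
#' @export
isotope_envelope <- function(comp, K = 6L) {
  stopifnot(inherits(comp, "elemental_composition"))
  if (K < 3L) stop("K must be at least 3")
  counts <- comp$counts
  if (sum(counts) == 0L) stop("empty composition")
  a <- c(1, numeric(K))
  for (el in names(counts)) {
    n <- counts[[el]]
    if (n > 0L)
      a <- .conv_trunc(a, .dist_power(.element_shift_dist(el), n, K), K)
  }
  structure(list(abundances = a,
                 monoisotopic_mass = comp$monoisotopic_mass,
                 spacing = ISOTOPE_SPACING,
                 label = comp$label),
            class = "isotope_envelope")
}

#' m/z positions of a light/heavy labeled peptide pair
#'
#' The light (16O sulfoxide) species' isotopologues sit at
#' `(M + k * spacing + z * m_proton) / z`; the heavy (18O) species is offset
#' by the 18O-16O mass difference, 2.004246 Da, divided by the charge. The
#' 0.0025 Da mismatch between two 13C spacings and the label offset is not
#' resolved at typical Orbitrap MS1 resolution, so heavy isotopologue k
#' coincides with light isotopologue k+2 for extraction purposes.
#'
#' @param envelope An `isotope_envelope` of the light species.
#' @param charge Positive integer charge state (the acquisition range in the
#'   assay is 2..5).
#' @return A `pair_geometry`: list with `light_mz`, `heavy_mz` (one per
#'   isotopologue index), `charge` and `label_offset`.
#' @export
pair_positions <- function(envelope, charge) {
  stopifnot(inherits(envelope, "isotope_envelope"))
  if (!is.numeric(charge) || length(charge) != 1L || charge <= 0 ||
      charge != round(charge))
    stop("charge must be a positive integer")
  k <- seq_along(envelope$abundances) - 1L
  light <- (envelope$monoisotopic_mass + k * envelope$spacing +
              charge * PROTON_MASS) / charge
  structure(list(light_mz = light,
                 heavy_mz = light + LABEL_OFFSET_18O / charge,
                 charge = as.integer(charge),
                 label_offset = LABEL_OFFSET_18O),
            class = "pair_geometry")
}

#' Channel-mixing coefficients for envelope-overlap correction
#'
#' Under the +2-position shift of the heavy envelope, light isotopologues
#' k >= 2 fall onto the heavy species' peak positions. Given index sets for
#' the summed light and heavy channels (indices on the light species' peak
#' axis; heavy isotopologue j sits at position j + 2), the expected
#' contribution of true light (L) and true heavy (H) species signal to each
#' channel is a sum of envelope abundances:
#' \deqn{w_{LL} = \sum_{k \in light} a_k, \quad
#'       w_{LH} = \sum_{k \in light} a_{k-2}, \quad
#'       w_{HL} = \sum_{k \in heavy} a_k, \quad
#'       w_{HH} = \sum_{k \in heavy} a_{k-2}.}
#'
#' @param envelope An `isotope_envelope`.
#' @param light_channel,heavy_channel Disjoint integer sets of 0-based peak
#'   positions on the light index axis.
#' @return A `mixing_coefficients` object: list with the four weights and
#'   the 2x2 mixing matrix `W` (rows = observed light/heavy channel,
#'   columns = true L/H signal).
#' @export
mixing_coefficients <- function(envelope, light_channel, heavy_channel) {
  stopifnot(inherits(envelope, "isotope_envelope"))
  light_channel <- as.integer(light_channel)
  heavy_channel <- as.integer(heavy_channel)
  if (length(intersect(light_channel, heavy_channel)) > 0L)
    stop("light and heavy channel index sets must be disjoint")
  if (any(c(light_channel, heavy_channel) < 0L))
    stop("channel indices must be nonnegative")
  a <- envelope$abundances
  at <- function(idx) {  # abundance at light-envelope index, 0 outside 0..K
    ok <- idx >= 0L & idx < length(a)
    sum(a[idx[ok] + 1L])
  }
  w <- c(light_L = at(light_channel), light_H = at(light_channel - 2L),
         heavy_L = at(heavy_channel), heavy_H = at(heavy_channel - 2L))
  W <- matrix(w, nrow = 2, byrow = TRUE,
              dimnames = list(c("light_channel", "heavy_channel"),
                              c("L", "H")))
  structure(list(light_channel_weight_L = w[["light_L"]],
                 light_channel_weight_H = w[["light_H"]],
                 heavy_channel_weight_L = w[["heavy_L"]],
                 heavy_channel_weight_H = w[["heavy_H"]],
                 W = W),
            class = "mixing_coefficients")
}
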