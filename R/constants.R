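# Physical constants used throughout the quantification.
# Masses in Da. The label offset is the 18O - 16O mass difference; the
# isotopologue spacing is the averaged ~13C neutron-addition spacing used
# for aggregated (unit-mass-binned) envelopes.

PROTON_MASS <- 1.00727646688
ISOTOPE_SPACING <- 1.00335
LABEL_OFFSET_18O <- 2.004246

# cache for the packaged element isotope table
.mosquant_env <- new.env(parent = emptyenv())

#' Natural isotope abundances of the peptide-forming elements
#'
#' Returns the pinned table of isotope masses and natural abundances for
#' C, H, N, O and S that all envelope computations use. The table is shipped
#' as a plain-text resource so the numerical basis of every theoretical
#' envelope is fixed and inspectable.
#'
#' @return A data.frame with columns `element`, `shift` (nominal neutron
#'   count above the lightest isotope), `mass` (Da) and `abundance`.
#' @export
element_isotopes <- function() {
  if (is.null(.mosquant_env$isotopes)) {
    path <- system.file("extdata", "element_isotopes.tsv", package = "mosquant")
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    .mosquant_env$isotopes <- tab
  }
  .mosquant_env$isotopes
}

# monoisotopic mass of one atom of each element
.element_mono_mass <- function() {
  tab <- element_isotopes()
  tab <- tab[tab$shift == 0, ]
  stats::setNames(tab$mass, tab$element)
}

# per-element distribution over nominal mass shifts, as a dense numeric
# vector starting at shift 0
.element_shift_dist <- function(element) {
  tab <- element_isotopes()
  tab <- tab[tab$element == element, ]
  out <- numeric(max(tab$shift) + 1L)
  out[tab$shift + 1L] <- tab$abundance
  out / sum(out)
}
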