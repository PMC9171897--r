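# Elemental compositions of peptides and the recognized modifications.

# Residue compositions (monomer minus water), counts of C, H, N, O, S.
.AA_COMPOSITIONS <- matrix(
  c( # C   H  N  O  S
     2,  3, 1, 1, 0,  # G
     3,  5, 1, 1, 0,  # A
     3,  5, 1, 2, 0,  # S
     5,  7, 1, 1, 0,  # P
     5,  9, 1, 1, 0,  # V
     4,  7, 1, 2, 0,  # T
     3,  5, 1, 1, 1,  # C
     6, 11, 1, 1, 0,  # L
     6, 11, 1, 1, 0,  # I
     4,  6, 2, 2, 0,  # N
     4,  5, 1, 3, 0,  # D
     5,  8, 2, 2, 0,  # Q
     6, 12, 2, 1, 0,  # K
     5,  7, 1, 3, 0,  # E
     5,  9, 1, 1, 1,  # M
     6,  7, 3, 1, 0,  # H
     9,  9, 1, 1, 0,  # F
     6, 12, 4, 1, 0,  # R
     9,  9, 1, 2, 0,  # Y
    11, 10, 2, 1, 0), # W
  ncol = 5, byrow = TRUE,
  dimnames = list(c("G","A","S","P","V","T","C","L","I","N",
                    "D","Q","K","E","M","H","F","R","Y","W"),
                  c("C","H","N","O","S")))

# Composition deltas of the recognized modifications.
.MOD_DELTAS <- list(
  mso16       = c(C = 0, H = 0, N = 0, O = 1, S = 0),  # Met sulfoxide, 16O
  mso18       = c(C = 0, H = 0, N = 0, O = 1, S = 0),  # Met sulfoxide, 18O
  acetyl_nterm = c(C = 2, H = 2, N = 0, O = 1, S = 0),
  cam_cys     = c(C = 2, H = 3, N = 1, O = 1, S = 0)   # carbamidomethyl, per Cys
)

#' Elemental composition of a (modified) peptide
#'
#' Sums residue compositions, adds one water, and applies the recognized
#' modifications: methionine sulfoxide with a 16O (`"mso16"`) or 18O
#' (`"mso18"`) oxygen, N-terminal acetylation (`"acetyl_nterm"`), and
#' carbamidomethylated cysteine (`"cam_cys"`, applied once per Cys residue).
#' The sulfoxide adds exactly one oxygen and sets the isotope label of the
#' species; light and heavy species of the same peptide therefore have
#' identical element counts and differ only in which oxygen isotope occupies
#' the sulfoxide position.
#'
#' @param sequence Amino-acid string using the 20 standard one-letter codes.
#' @param modifications Character vector of modification tokens from the
#'   recognized set above. At most one of `"mso16"`/`"mso18"` may be given.
#' @return An object of class `elemental_composition`: a list with integer
#'   `counts` (named C, H, N, O, S), `label` (`"light16O"`, `"heavy18O"` or
#'   `NA`), and `monoisotopic_mass` in Da (including the label-oxygen mass).
#' @export
composition_from_sequence <- function(sequence, modifications = character()) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  residues <- strsplit(sequence, "")[[1]]
  unknown <- setdiff(residues, rownames(.AA_COMPOSITIONS))
  if (length(unknown) > 0L)
    stop("unknown residue(s): ", paste(unique(unknown), collapse = ", "))
  bad <- setdiff(modifications, names(.MOD_DELTAS))
  if (length(bad) > 0L)
    stop("unknown modification(s): ", paste(unique(bad), collapse = ", "))
  if (all(c("mso16", "mso18") %in% modifications))
    stop("a species cannot carry both a 16O and an 18O sulfoxide label")

  counts <- colSums(.AA_COMPOSITIONS[residues, , drop = FALSE])
  counts <- counts + c(C = 0, H = 2, N = 0, O = 1, S = 0)  # one water

  label <- NA_character_
  for (mod in modifications) {
    delta <- .MOD_DELTAS[[mod]]
    if (mod == "cam_cys") {
      n_cys <- sum(residues == "C")
      if (n_cys == 0L) stop("cam_cys requires a cysteine in the sequence")
      delta <- delta * n_cys
    }
    if (mod %in% c("mso16", "mso18")) {
      if (!any(residues == "M")) stop("sulfoxide requires a methionine")
      label <- if (mod == "mso16") "light16O" else "heavy18O"
    }
    counts <- counts + delta
  }

  mono <- sum(counts * .element_mono_mass()[names(counts)])
  if (identical(label, "heavy18O")) mono <- mono + LABEL_OFFSET_18O

  structure(list(counts = as.integer(counts) |> stats::setNames(names(counts)),
                 label = label,
                 monoisotopic_mass = mono),
            class = "elemental_composition")
}

#' @export
print.elemental_composition <- function(x, ...) {
  formula <- paste0(names(x$counts)[x$counts > 0], x$counts[x$counts > 0],
                    collapse = "")
  cat("<elemental_composition> ", formula,
      sprintf("  mono %.4f Da", x$monoisotopic_mass),
      if (!is.na(x$label)) paste0("  [", x$label, "]") else "", "\n", sep = "")
  invisible(x)
}
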