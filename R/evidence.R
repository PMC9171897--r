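# Evidence-table ingestion: search-engine identification exports define the
# extraction targets.

.EVIDENCE_ALIASES <- list(
  sequence = c("sequence"),
  modifications = c("modifications", "modified.sequence.modifications"),
  charge = c("charge"),
  mz = c("mz", "m.z", "m.z."),
  rt = c("rt", "retention.time", "retention_time"),
  raw_file = c("raw_file", "raw.file", "run"),
  score = c("score", "intensity")
)

.normalize_mod_token <- function(x) {
  if (is.na(x) || !nzchar(x) || grepl("^unmodified$", x, ignore.case = TRUE))
    return(NA_character_)
  toks <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  mapped <- vapply(toks, function(tk) {
    if (tk %in% c("mso16", "mso18", "acetyl_nterm", "cam_cys")) return(tk)
    if (grepl("18O", tk)) return("mso18")
    if (grepl("16O", tk) || grepl("oxidation", tk, ignore.case = TRUE))
      return("mso16")
    if (grepl("acetyl", tk, ignore.case = TRUE)) return("acetyl_nterm")
    if (grepl("carbamidomethyl", tk, ignore.case = TRUE)) return("cam_cys")
    NA_character_
  }, character(1))
  mapped <- mapped[!is.na(mapped)]
  if (length(mapped) == 0L) return(NA_character_)
  paste(unique(mapped), collapse = ";")
}

#' Read a peptide-identification evidence table
#'
#' Parses a tab-separated search-engine evidence export. Required columns
#' (matched case-insensitively against common aliases): sequence,
#' modifications, charge, m/z, retention time, raw file. Unknown columns
#' are ignored. Records outside the acquisition charge range 2-5 are
#' skipped; duplicate (sequence, charge, run) rows are collapsed to one
#' extraction target, keeping the highest-scoring row.
#'
#' @param path Path to a TSV file.
#' @param charge_range Accepted charge states (default 2:5).
#' @return Data.frame with columns `peptide`, `sequence`, `modifications`
#'   (normalized tokens), `charge`, `mz`, `rt`, `raw_file`, `score`, plus
#'   attributes `n_rows_read` and `n_skipped_charge`.
#' @export
read_evidence <- function(path, charge_range = 2:5) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  cols <- tolower(make.names(names(raw)))
  pick <- function(field) {
    hit <- which(cols %in% .EVIDENCE_ALIASES[[field]])
    if (length(hit) == 0L) return(NULL)
    raw[[hit[1]]]
  }
  out <- list()
  for (field in names(.EVIDENCE_ALIASES)) {
    v <- pick(field)
    if (is.null(v) && !field %in% c("score", "modifications"))
      stop("missing required evidence column: ", field)
    out[[field]] <- v
  }
  if (is.null(out$score)) out$score <- rep(0, nrow(raw))
  if (is.null(out$modifications)) out$modifications <- rep(NA_character_, nrow(raw))
  ev <- data.frame(sequence = as.character(out$sequence),
                   modifications = as.character(out$modifications),
                   charge = as.integer(out$charge),
                   mz = as.numeric(out$mz),
                   rt = as.numeric(out$rt),
                   raw_file = as.character(out$raw_file),
                   score = as.numeric(out$score),
                   stringsAsFactors = FALSE)
  n_read <- nrow(ev)
  in_range <- ev$charge %in% charge_range
  n_skip <- sum(!in_range)
  if (n_skip > 0L)
    message(n_skip, " record(s) outside charge range ",
            min(charge_range), "-", max(charge_range), " skipped")
  ev <- ev[in_range, , drop = FALSE]
  ev$modifications <- vapply(ev$modifications, .normalize_mod_token,
                             character(1), USE.NAMES = FALSE)

  # collapse to one extraction target per (sequence, charge, run)
  key <- paste(ev$sequence, ev$charge, ev$raw_file, sep = "\r")
  ev <- ev[order(key, -ev$score), ]
  ev <- ev[!duplicated(paste(ev$sequence, ev$charge, ev$raw_file, sep = "\r")), ]
  ev$peptide <- ev$sequence
  rownames(ev) <- NULL
  ev <- ev[, c("peptide", "sequence", "modifications", "charge", "mz", "rt",
               "raw_file", "score")]
  attr(ev, "n_rows_read") <- n_read
  attr(ev, "n_skipped_charge") <- n_skip
  ev
}
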