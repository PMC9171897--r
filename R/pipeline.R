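# Pipeline orchestration: extraction -> ratio -> titration -> statistics,
# with filter-gate accounting and result serialization.

#' Run the full quantification pipeline
#'
#' Executes every stage on a set of MS1 runs: per-run pair quantification,
#' validity filtering and titration-response fitting per grouping (young,
#' old, interage), adaptive-shrinkage flagging of oxidation-prone
#' methionines on the interage estimates, and Holm-corrected age contrasts.
#' Every record dropped at any gate is accounted for in the summary.
#'
#' @param runs Named list of [ms1_map()] objects, or a character vector of
#'   mzML/mzXML paths (names become run ids).
#' @param evidence Evidence data.frame ([read_evidence()] or the simulator's
#'   evidence table).
#' @param design Design table with columns `run`, `t`, `technical_rep`,
#'   `biological_rep`, `age_group`.
#' @param config A [mos_config()].
#' @return A `mos_results` bundle: `pair_quants`, `estimates` (named list
#'   per grouping), `oxidation_prone`, `age_contrasts`, `summary`, `config`.
#' @export
run_pipeline <- function(runs, evidence, design, config = mos_config()) {
  validate_config(config)
  if (is.character(runs)) {
    paths <- runs
    ids <- if (!is.null(names(paths))) names(paths) else
      sub("\\.[^.]+$", "", basename(paths))
    runs <- lapply(seq_along(paths), function(i) read_ms1(paths[i], ids[i]))
    names(runs) <- ids
  }
  age_groups <- unique(design$age_group)

  if (nrow(evidence) == 0L) {
    warning("empty evidence table: nothing to quantify")
    empty_est <- data.frame(peptide = character(0), grouping = character(0),
                            mos_invivo = numeric(0), sem = numeric(0),
                            nrmse = numeric(0), n_valid = integer(0),
                            pass = logical(0))
    return(structure(list(pair_quants = .pq_empty(),
                          estimates = stats::setNames(
                            rep(list(empty_est), length(age_groups) + 1L),
                            c(age_groups, "interage")),
                          oxidation_prone = NULL, age_contrasts = NULL,
                          summary = list(n_evidence_targets = 0L),
                          config = config),
                     class = "mos_results"))
  }

  # one extraction target per (peptide, charge, run)
  key <- paste(evidence$sequence, evidence$charge, evidence$raw_file,
               sep = "\r")
  targets <- evidence[!duplicated(key), , drop = FALSE]
  if (is.null(targets$peptide)) targets$peptide <- targets$sequence

  pq <- do.call(rbind, lapply(names(runs), function(id) {
    tgt <- targets[targets$raw_file == id, , drop = FALSE]
    if (nrow(tgt) == 0L) return(NULL)
    quantify_run(runs[[id]], tgt, config)
  }))
  if (is.null(pq)) stop("no evidence targets matched any run")

  seqs <- stats::setNames(targets$sequence, targets$peptide)
  seqs <- seqs[!duplicated(names(seqs))]
  bundle <- analyze_pair_quants(pq, design, config, sequences = seqs)
  bundle$summary <- c(list(n_evidence_rows = nrow(evidence),
                           n_evidence_targets = nrow(targets)),
                      bundle$summary)
  bundle
}

#' Downstream analysis of a PairQuant table
#'
#' Runs every stage after per-run quantification: validity filters and
#' peptide assembly, titration fits per grouping, oxidation-prone flagging
#' and age contrasts, with filter-gate accounting. [run_pipeline()] is this
#' function applied to freshly quantified runs; calling it directly supports
#' re-analysis of a saved PairQuant table.
#'
#' @param pq PairQuant data.frame ([quantify_run()] rows).
#' @param design Design table.
#' @param config A [mos_config()].
#' @param sequences Named character vector mapping peptide ids to sequences.
#' @return A `mos_results` bundle (without evidence-level counts).
#' @export
analyze_pair_quants <- function(pq, design, config = mos_config(),
                                sequences = NULL) {
  age_groups <- unique(design$age_group)
  assembled <- assemble_peptide_table(pq, design,
                                      min_valid = config$min_valid,
                                      drop_cysteine = config$drop_cysteine,
                                      sequences = sequences)

  groupings <- c(age_groups, "interage")
  estimates <- lapply(groupings, function(g)
    estimate_mos(assembled, grouping = g, config = config))
  names(estimates) <- groupings

  interage <- estimates[["interage"]]
  oxprone <- if (nrow(interage) > 0L)
    suppressWarnings(flag_oxidation_prone(interage,
                                          q_threshold = config$q_threshold))
  else NULL

  contrasts <- if (length(age_groups) == 2L)
    age_contrast(estimates[[age_groups[1]]], estimates[[age_groups[2]]],
                 alpha = config$q_threshold)
  else NULL

  inv <- pq[!pq$valid, ]
  reason_counts <- if (nrow(inv) > 0L) as.list(table(inv$reason)) else list()
  drop_tab <- table(factor(assembled$dropped$reason,
                           levels = c("cysteine-containing", "below min_valid")))
  est_summary <- lapply(estimates, function(e)
    list(n = nrow(e), n_pass = sum(e$pass),
         n_fail_nrmse = sum(!e$pass & !is.na(e$nrmse))))
  summary <- list(
    n_pair_quants = nrow(pq),
    n_pair_quants_valid = sum(pq$valid),
    n_pair_quants_invalid = sum(!pq$valid),
    invalid_reasons = reason_counts,
    n_peptides_quantified = length(unique(pq$peptide)),
    n_dropped_cysteine = unname(drop_tab[["cysteine-containing"]]),
    n_dropped_min_valid = unname(drop_tab[["below min_valid"]]),
    n_peptides_retained = length(unique(assembled$measurements$peptide)),
    estimates = est_summary,
    global_median = if (!is.null(oxprone)) attr(oxprone, "global_median")
      else NA_real_,
    n_oxidation_prone = if (!is.null(oxprone)) sum(oxprone$significant)
      else 0L,
    n_age_significant = if (!is.null(contrasts)) sum(contrasts$significant)
      else 0L,
    mean_mos_interage = if (nrow(interage) > 0L)
      mean(interage$mos_invivo[interage$pass]) else NA_real_)

  structure(list(pair_quants = pq, estimates = estimates,
                 oxidation_prone = oxprone, age_contrasts = contrasts,
                 summary = summary, config = config),
            class = "mos_results")
}

#' @export
print.mos_results <- function(x, ...) {
  s <- x$summary
  cat("<mos_results>\n")
  cat(sprintf("  pair quants: %d (%d valid)\n",
              s$n_pair_quants %||% 0L, s$n_pair_quants_valid %||% 0L))
  cat(sprintf("  peptides retained: %d (dropped: %d Cys, %d below min_valid)\n",
              s$n_peptides_retained %||% 0L, s$n_dropped_cysteine %||% 0L,
              s$n_dropped_min_valid %||% 0L))
  if (!is.null(s$global_median) && !is.na(s$global_median))
    cat(sprintf("  interage global median MOS: %.4f\n", s$global_median))
  cat(sprintf("  oxidation-prone: %d; age-significant: %d\n",
              s$n_oxidation_prone %||% 0L, s$n_age_significant %||% 0L))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a results bundle to disk
#'
#' Emits the PairQuant table, one MOSEstimate table per grouping, the
#' oxidation-prone and age-contrast tables, the summary as JSON and the
#' configuration used — a deterministic file set with documented columns.
#'
#' @param bundle A `mos_results` from [run_pipeline()].
#' @param outdir Output directory (created if needed).
#' @return Character vector of paths written, invisibly.
#' @export
write_results <- function(bundle, outdir) {
  stopifnot(inherits(bundle, "mos_results"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  wt <- function(df, name) {
    f <- file.path(outdir, name)
    utils::write.table(df, f, sep = "\t", row.names = FALSE, quote = FALSE)
    f
  }
  paths <- wt(bundle$pair_quants, "pair_quants.tsv")
  for (g in names(bundle$estimates))
    paths <- c(paths, wt(bundle$estimates[[g]],
                         paste0("estimates_", g, ".tsv")))
  if (!is.null(bundle$oxidation_prone))
    paths <- c(paths, wt(bundle$oxidation_prone, "oxidation_prone.tsv"))
  if (!is.null(bundle$age_contrasts))
    paths <- c(paths, wt(bundle$age_contrasts, "age_contrasts.tsv"))
  sj <- file.path(outdir, "summary.json")
  jsonlite::write_json(bundle$summary, sj, auto_unbox = TRUE, digits = NA,
                       null = "null")
  cj <- file.path(outdir, "config.json")
  write_config(bundle$config, cj)
  invisible(c(paths, sj, cj))
}
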