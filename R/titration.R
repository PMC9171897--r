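# Titration-response modeling: pool per-run MOS values, apply validity
# filters, and extrapolate to zero carrier fraction.

#' Build a titration experiment design table
#'
#' The assay's design: two titration points (carrier fractions 0.10 and
#' 0.25), two technical replicates of each, three biological replicates per
#' age group — 12 runs per age group.
#'
#' @param t_points Carrier proteome fractions (default `c(0.10, 0.25)`).
#' @param n_technical Technical replicates per titration point (default 2).
#' @param n_biological Biological replicates per age group (default 3).
#' @param age_groups Age-group labels (default `c("young", "old")`).
#' @return Data.frame with columns `run`, `t`, `technical_rep`,
#'   `biological_rep`, `age_group`.
#' @export
make_titration_design <- function(t_points = c(0.10, 0.25),
                                  n_technical = 2L, n_biological = 3L,
                                  age_groups = c("young", "old")) {
  grid <- expand.grid(technical_rep = seq_len(n_technical),
                      t = t_points,
                      biological_rep = seq_len(n_biological),
                      age_group = age_groups,
                      stringsAsFactors = FALSE)
  grid$run <- sprintf("%s_b%d_t%02d_r%d", grid$age_group,
                      grid$biological_rep, round(grid$t * 100),
                      grid$technical_rep)
  grid[, c("run", "t", "technical_rep", "biological_rep", "age_group")]
}

#' Assemble per-peptide measurement sets with validity filters
#'
#' Joins PairQuant rows to the design, then applies the assay's inclusion
#' rules: a peptide must have at least `min_valid` valid values in every age
#' group (7 out of a possible 12 in the reference design), and
#' cysteine-containing peptides are removed (cysteine oxidation is
#' chemically reversible during processing, so the blocking strategy cannot
#' quantify it).
#'
#' @param pair_quants Data.frame of PairQuant rows ([quantify_run()]).
#' @param design Design table ([make_titration_design()]); every run present
#'   in `pair_quants` must appear in it.
#' @param min_valid Minimum valid values per age group (default 7).
#' @param drop_cysteine Remove peptides whose sequence contains `C`.
#' @param sequences Optional named character vector mapping peptide ids to
#'   sequences; defaults to treating the peptide id itself as the sequence.
#' @return List with `measurements` (valid rows joined to the design, for
#'   retained peptides), and `dropped` (data.frame peptide/reason for every
#'   excluded peptide).
#' @export
assemble_peptide_table <- function(pair_quants, design, min_valid = 7L,
                                   drop_cysteine = TRUE, sequences = NULL) {
  missing_runs <- setdiff(unique(pair_quants$run), design$run)
  if (length(missing_runs) > 0L)
    stop("run(s) absent from design: ", paste(missing_runs, collapse = ", "))
  if (is.null(sequences)) {
    ids <- unique(pair_quants$peptide)
    sequences <- stats::setNames(ids, ids)
  }

  dropped <- data.frame(peptide = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  keep <- unique(pair_quants$peptide)

  if (drop_cysteine) {
    cys <- keep[grepl("C", sequences[keep], fixed = TRUE)]
    if (length(cys) > 0L) {
      dropped <- rbind(dropped, data.frame(peptide = cys,
                                           reason = "cysteine-containing",
                                           stringsAsFactors = FALSE))
      keep <- setdiff(keep, cys)
    }
  }

  merged <- merge(pair_quants[pair_quants$peptide %in% keep, ], design,
                  by = "run")
  valid <- merged[merged$valid, ]
  counts <- table(factor(valid$peptide, levels = keep),
                  factor(valid$age_group, levels = unique(design$age_group)))
  enough <- rownames(counts)[apply(counts >= min_valid, 1, all)]
  too_few <- setdiff(keep, enough)
  if (length(too_few) > 0L)
    dropped <- rbind(dropped, data.frame(peptide = too_few,
                                         reason = "below min_valid",
                                         stringsAsFactors = FALSE))

  list(measurements = valid[valid$peptide %in% enough, ],
       dropped = dropped)
}

#' Fit a peptide's titration response
#'
#' Models the measured stoichiometry of peptide j in run i as the carrier
#' mixing equation
#' \deqn{MOS_{ij} = t_i + (1 - t_i)\,MOS_{invivo,j}}
#' where `t_i` is the known carrier-proteome fraction of run i and
#' `MOS_invivo` is the peptide's stoichiometry extrapolated to `t = 0`. The
#' parameter is estimated by bounded nonlinear least squares on \[0, 1\];
#' its standard error comes from the fit's parameter covariance. The fit
#' quality is the normalized RMSE: residual RMSE divided by the mean (or
#' range) of the observed values; the quality gate is NRMSE <= 0.2.
#'
#' @param t Carrier fractions, one per measurement, in \[0, 1).
#' @param mos Measured per-run MOS values.
#' @param nrmse_threshold Pass threshold (default 0.2).
#' @param nrmse_normalizer `"mean"` (default) or `"range"`.
#' @param clip_measurements Clip observed MOS into \[0,1\] before fitting.
#' @return List: `mos_invivo`, `sem`, `nrmse`, `n`, `pass`.
#' @export
fit_titration_response <- function(t, mos, nrmse_threshold = 0.2,
                                   nrmse_normalizer = c("mean", "range"),
                                   clip_measurements = FALSE) {
  nrmse_normalizer <- match.arg(nrmse_normalizer)
  ok <- !is.na(t) & !is.na(mos)
  t <- t[ok]; mos <- mos[ok]
  if (length(t) < 3L) stop("need at least 3 measurements")
  if (length(unique(t)) < 2L) stop("degenerate design: all t identical")
  if (any(t < 0 | t >= 1)) stop("t must lie in [0, 1)")
  if (clip_measurements) mos <- pmin(1, pmax(0, mos))

  df <- data.frame(t = t, mos = mos)
  # closed-form weighted start (model is linear in the parameter)
  m0 <- sum((1 - t) * (mos - t)) / sum((1 - t)^2)
  # port emits a spurious convergence warning when the optimum sits on a
  # bound (common: truly unoxidized peptides have mos_invivo = 0)
  fit <- tryCatch(
    suppressWarnings(
    stats::nls(mos ~ t + (1 - t) * m, data = df,
               start = list(m = min(1, max(0, m0))),
               lower = 0, upper = 1, algorithm = "port",
               control = stats::nls.control(warnOnly = TRUE))),
    error = function(e) NULL)
  if (is.null(fit)) {
    m_hat <- min(1, max(0, m0))
    resid <- mos - (t + (1 - t) * m_hat)
    sem <- sqrt(sum(resid^2) / max(1, length(t) - 1) / sum((1 - t)^2))
  } else {
    m_hat <- stats::coef(fit)[["m"]]
    sem <- tryCatch(summary(fit)$coefficients["m", "Std. Error"],
                    error = function(e) NA_real_)
    resid <- stats::residuals(fit)
  }
  rmse <- sqrt(mean(resid^2))
  normalizer <- switch(nrmse_normalizer,
                       mean = mean(mos),
                       range = diff(range(mos)))
  nrmse <- if (rmse == 0) 0 else if (normalizer > 0) rmse / normalizer else Inf
  list(mos_invivo = m_hat, sem = sem, nrmse = nrmse, n = length(t),
       pass = is.finite(nrmse) && nrmse <= nrmse_threshold)
}

#' Per-peptide in vivo MOS estimates for a grouping
#'
#' Fits [fit_titration_response()] per peptide using either age-specific
#' grouping of the measurements (`"young"`, `"old"`) or all measurements
#' pooled (`"interage"`).
#'
#' @param assembled Output of [assemble_peptide_table()].
#' @param grouping `"interage"` (default) or one of the age-group labels.
#' @param config A [mos_config()] supplying the NRMSE gate.
#' @return Data.frame (MOSEstimate records): `peptide`, `grouping`,
#'   `mos_invivo`, `sem`, `nrmse`, `n_valid`, `pass`.
#' @export
estimate_mos <- function(assembled, grouping = "interage",
                         config = mos_config()) {
  meas <- assembled$measurements
  if (grouping != "interage") meas <- meas[meas$age_group == grouping, ]
  peptides <- unique(meas$peptide)
  if (length(peptides) == 0L)
    return(data.frame(peptide = character(0), grouping = character(0),
                      mos_invivo = numeric(0), sem = numeric(0),
                      nrmse = numeric(0), n_valid = integer(0),
                      pass = logical(0), stringsAsFactors = FALSE))
  rows <- lapply(peptides, function(p) {
    m <- meas[meas$peptide == p, ]
    fit <- tryCatch(
      fit_titration_response(m$t, m$mos,
                             nrmse_threshold = config$nrmse_threshold,
                             nrmse_normalizer = config$nrmse_normalizer,
                             clip_measurements = config$clip_measurements),
      error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(peptide = p, grouping = grouping,
                        mos_invivo = NA_real_, sem = NA_real_,
                        nrmse = NA_real_, n_valid = nrow(m), pass = FALSE,
                        stringsAsFactors = FALSE))
    data.frame(peptide = p, grouping = grouping, mos_invivo = fit$mos_invivo,
               sem = fit$sem, nrmse = fit$nrmse, n_valid = fit$n,
               pass = fit$pass, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
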