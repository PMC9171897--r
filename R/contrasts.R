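# Two-sample age contrasts with Holm-Bonferroni family-wise error control.

#' Holm-Bonferroni step-down adjustment
#'
#' Thin validated wrapper over `stats::p.adjust(method = "holm")`; input
#' order is preserved and monotonicity is enforced by the step-down
#' construction.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order.
#' @export
holm_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues) | pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "holm")
}

#' Age contrasts of in vivo MOS estimates
#'
#' For every peptide with a passing estimate in both age groups, the effect
#' is the difference in estimated in vivo MOS (old minus young); the pooled
#' standard error combines the two titration-fit SEMs; the t statistic is
#' effect / pooled SE with Welch-Satterthwaite degrees of freedom derived
#' from the per-group residual counts (n - 1 per group, floored at 3).
#' Family-wise error across peptides is controlled by Holm-Bonferroni.
#'
#' @param young,old MOSEstimate data.frames for the two groups.
#' @param alpha Significance level on the adjusted p-values (default 0.01).
#' @param se_floor Lower bound applied to SEMs (default 1e-8).
#' @return Data.frame (AgeContrast records): `peptide`, `mos_young`,
#'   `mos_old`, `effect`, `se_pooled`, `t`, `df`, `pvalue`, `p_holm`,
#'   `significant`.
#' @export
age_contrast <- function(young, old, alpha = 0.01, se_floor = 1e-8) {
  y <- young[young$pass & !is.na(young$mos_invivo), ]
  o <- old[old$pass & !is.na(old$mos_invivo), ]
  shared <- intersect(y$peptide, o$peptide)
  empty <- data.frame(peptide = character(0), mos_young = numeric(0),
                      mos_old = numeric(0), effect = numeric(0),
                      se_pooled = numeric(0), t = numeric(0), df = numeric(0),
                      pvalue = numeric(0), p_holm = numeric(0),
                      significant = logical(0))
  if (length(shared) == 0L) return(empty)
  y <- y[match(shared, y$peptide), ]
  o <- o[match(shared, o$peptide), ]

  se_y <- pmax(ifelse(is.na(y$sem), se_floor, y$sem), se_floor)
  se_o <- pmax(ifelse(is.na(o$sem), se_floor, o$sem), se_floor)
  se_pooled <- sqrt(se_y^2 + se_o^2)
  if (any(se_pooled <= 0)) stop("zero pooled standard error")
  effect <- o$mos_invivo - y$mos_invivo
  tstat <- effect / se_pooled

  df_y <- pmax(y$n_valid - 1L, 3L)
  df_o <- pmax(o$n_valid - 1L, 3L)
  df <- (se_y^2 + se_o^2)^2 / (se_y^4 / df_y + se_o^4 / df_o)
  pvalue <- 2 * stats::pt(-abs(tstat), df)
  p_holm <- holm_adjust(pvalue)

  data.frame(peptide = shared, mos_young = y$mos_invivo,
             mos_old = o$mos_invivo, effect = effect, se_pooled = se_pooled,
             t = tstat, df = df, pvalue = pvalue, p_holm = p_holm,
             significant = p_holm <= alpha, stringsAsFactors = FALSE)
}
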