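# Empirical-Bayes adaptive shrinkage with a half-uniform (positive-effects)
# mixture prior, for identifying oxidation-prone methionines.

#' Adaptive shrinkage with a half-uniform positive prior
#'
#' Fits, by EM maximum likelihood, the mixture prior
#' \deqn{\pi_0 \delta_0 + \sum_m \pi_m \, \mathrm{Uniform}(0, b_m)}
#' over a geometric grid of scales `b_m`, with likelihood
#' `effect_hat ~ Normal(effect, SE^2)`. Only positive true effects are
#' representable, matching a one-sample analysis that asks whether a site
#' lies above the global median. Each record's local false-sign rate (the
#' posterior probability that its true effect is not positive — here the
#' posterior weight on the point mass at zero) and q-value (running mean of
#' the sorted local false-sign rates) are returned.
#'
#' @param effects Observed effects (distances from the global median).
#' @param se Standard errors, all positive, same length.
#' @param grid Optional vector of uniform-component upper bounds; defaults
#'   to a geometric grid from `min(se)/10` to `2 * max(abs(effects))` with
#'   ratio sqrt(2).
#' @param nullweight Dirichlet pseudo-count favoring the null component
#'   (default 10, the convention of adaptive-shrinkage implementations);
#'   resolves the tie between the point mass and uniform components much
#'   narrower than the noise SD, which the likelihood cannot distinguish.
#' @param maxiter,tol EM iteration cap and penalized log-likelihood
#'   tolerance.
#' @return Data.frame with `effect`, `se`, `posterior_mean`, `lfsr`,
#'   `qvalue`; mixture weights and grid attached as attributes `pi` and
#'   `grid`.
#' @export
shrinkage_fit <- function(effects, se, grid = NULL, nullweight = 10,
                          maxiter = 2000L, tol = 1e-10) {
  n <- length(effects)
  stopifnot(length(se) == n)
  if (any(!is.finite(se) | se <= 0)) stop("all SEs must be positive")

  if (is.null(grid)) {
    lo <- min(se) / 10
    hi <- max(2 * max(abs(effects)), lo * 2)
    grid <- lo * sqrt(2)^(0:ceiling(log(hi / lo) / log(sqrt(2))))
  }
  M <- length(grid)

  # component likelihood matrix: col 1 = point mass at 0, cols 2..M+1 =
  # Uniform(0, b_m) convolved with the Normal noise
  L <- matrix(0, n, M + 1L)
  L[, 1] <- stats::dnorm(effects, 0, se)
  for (m in seq_len(M))
    L[, m + 1L] <- (stats::pnorm(effects / se) -
                    stats::pnorm((effects - grid[m]) / se)) / grid[m]
  L <- pmax(L, 1e-300)

  pi_hat <- rep(1 / (M + 1L), M + 1L)
  pseudo <- c(nullweight - 1, rep(0, M))
  ll_old <- -Inf
  for (it in seq_len(maxiter)) {
    num <- sweep(L, 2, pi_hat, `*`)
    rowsum_ <- rowSums(num)
    resp <- num / rowsum_
    pi_hat <- (colSums(resp) + pseudo) / (n + nullweight - 1)
    ll <- sum(log(rowsum_)) + (nullweight - 1) * log(max(pi_hat[1], 1e-300))
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }

  # posterior means: E[beta | component m] for the truncated-normal
  # posterior on (0, b_m); 0 for the null component
  post_mean_comp <- matrix(0, n, M + 1L)
  for (m in seq_len(M)) {
    b <- grid[m]
    alpha <- (0 - effects) / se
    beta_ <- (b - effects) / se
    Z <- stats::pnorm(beta_) - stats::pnorm(alpha)
    pm <- effects + se * (stats::dnorm(alpha) - stats::dnorm(beta_)) / pmax(Z, 1e-300)
    post_mean_comp[, m + 1L] <- pmin(b, pmax(0, pm))
  }
  posterior_mean <- rowSums(resp * post_mean_comp)

  lfsr <- resp[, 1]  # P(effect <= 0 | data): all non-null mass is positive
  ord <- order(lfsr)
  q_sorted <- cumsum(lfsr[ord]) / seq_len(n)
  qvalue <- numeric(n)
  qvalue[ord] <- pmin(1, q_sorted)

  out <- data.frame(effect = effects, se = se,
                    posterior_mean = posterior_mean,
                    lfsr = lfsr, qvalue = qvalue)
  attr(out, "pi") <- pi_hat
  attr(out, "grid") <- grid
  out
}

#' Flag oxidation-prone methionines
#'
#' A one-sample analysis on the interage estimates: effects are each
#' peptide's in vivo MOS reformatted as its distance from the global median
#' of the filtered set; standard errors are the titration-fit SEMs (floored
#' at `se_floor` so that numerically perfect fits remain usable). A site is
#' oxidation-prone when its adaptive-shrinkage q-value is at or below
#' `q_threshold` (default 0.01).
#'
#' @param estimates Interage MOSEstimate data.frame (rows with `pass` TRUE
#'   are used).
#' @param q_threshold Significance cutoff (default 0.01).
#' @param se_floor Lower bound applied to SEMs (default 1e-8).
#' @return Data.frame (EffectRecord): `peptide`, `mos_invivo`, `effect`,
#'   `se`, `lfsr`, `qvalue`, `significant`; the global median is attached as
#'   attribute `global_median`.
#' @export
flag_oxidation_prone <- function(estimates, q_threshold = 0.01,
                                 se_floor = 1e-8) {
  est <- estimates[estimates$pass & !is.na(estimates$mos_invivo), ]
  if (nrow(est) == 0L)
    return(structure(data.frame(peptide = character(0), mos_invivo = numeric(0),
                                effect = numeric(0), se = numeric(0),
                                lfsr = numeric(0), qvalue = numeric(0),
                                significant = logical(0)),
                     global_median = NA_real_))
  if (nrow(est) < 50L)
    warning("fewer than 50 records: shrinkage grid may be unstable")
  med <- stats::median(est$mos_invivo)
  eff <- est$mos_invivo - med
  se <- pmax(ifelse(is.na(est$sem), se_floor, est$sem), se_floor)
  fit <- shrinkage_fit(eff, se)
  out <- data.frame(peptide = est$peptide, mos_invivo = est$mos_invivo,
                    effect = eff, se = se, lfsr = fit$lfsr,
                    qvalue = fit$qvalue,
                    significant = fit$qvalue <= q_threshold,
                    stringsAsFactors = FALSE)
  attr(out, "global_median") <- med
  out
}
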