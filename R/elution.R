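# Gaussian / Gaussian-mixture elution-profile fitting in the retention-time
# dimension.

.gauss_mix <- function(rt, mu, sigma, A) {
  y <- numeric(length(rt))
  for (i in seq_along(mu))
    y <- y + A[i] * exp(-(rt - mu[i])^2 / (2 * sigma[i]^2))
  y
}

# starting values: component means at the top local maxima of the trace
.elution_starts <- function(rt, y, ncomp) {
  n <- length(y)
  is_max <- y > 0 &
    y >= c(-Inf, y[-n]) &
    y >= c(y[-1], -Inf)
  peaks <- order(y * is_max, decreasing = TRUE)[seq_len(min(ncomp, sum(is_max)))]
  peaks <- peaks[y[peaks] > 0]
  while (length(peaks) < ncomp)  # pad with the global max if too few maxima
    peaks <- c(peaks, which.max(y))
  span <- diff(range(rt))
  list(mu = rt[peaks], sigma = rep(max(span / 10, 1e-3), ncomp),
       A = pmax(y[peaks], max(y) / 10))
}

.fit_ncomp <- function(rt, y, ncomp) {
  st <- .elution_starts(rt, y, ncomp)
  scan_dt <- if (length(rt) > 1) min(diff(rt)) else 1e-3
  par0 <- c(st$mu, st$sigma, st$A)
  lower <- c(rep(min(rt), ncomp), rep(scan_dt / 2, ncomp), rep(0, ncomp))
  upper <- c(rep(max(rt), ncomp), rep(diff(range(rt)) + scan_dt, ncomp),
             rep(max(y) * 10, ncomp))
  resid_fn <- function(p) {
    mu <- p[1:ncomp]; sg <- p[(ncomp + 1):(2 * ncomp)]
    A <- p[(2 * ncomp + 1):(3 * ncomp)]
    y - .gauss_mix(rt, mu, sg, A)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                       fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- fit$par
  rss <- sum(fit$fvec^2)
  list(mu = p[1:ncomp], sigma = p[(ncomp + 1):(2 * ncomp)],
       A = p[(2 * ncomp + 1):(3 * ncomp)], rss = rss)
}

#' Fit an elution profile to an extracted trace
#'
#' Least-squares fit of 1..`max_components` Gaussian components to the raw
#' per-scan intensities; the number of components is chosen by BIC. Mixture
#' components absorb co-eluting interferences; the component whose mean is
#' nearest the predicted retention time is selected as the peptide's peak.
#' Fitting delineates the elution peak (its ±3 sigma bounds); downstream
#' quantification keeps using the raw trace intensities inside those bounds.
#'
#' @param rt Scan retention times, minutes.
#' @param intensity Per-scan intensities of the trace being fit.
#' @param max_components Maximum number of Gaussian components (default 3).
#' @param rt_predicted Predicted retention time used to select the
#'   component; defaults to the trace's intensity-weighted mean.
#' @param min_points Minimum number of nonzero scans required (default 5).
#' @return An `elution_fit`: list with `valid`, `reason`, `n_components`,
#'   `mu`, `sigma`, `A` vectors, `selected` (component index), `bounds`
#'   (selected mean ± 3 sigma, clipped to the window) and `goodness`
#'   (1 - RSS/TSS).
#' @export
fit_elution_profile <- function(rt, intensity, max_components = 3L,
                                rt_predicted = NULL, min_points = 5L) {
  invalid <- function(reason)
    structure(list(valid = FALSE, reason = reason, n_components = 0L,
                   mu = numeric(0), sigma = numeric(0), A = numeric(0),
                   selected = NA_integer_, bounds = c(NA_real_, NA_real_),
                   goodness = NA_real_),
              class = "elution_fit")
  if (length(rt) != length(intensity)) stop("rt and intensity lengths differ")
  if (sum(intensity > 0) < min_points) return(invalid("insufficient nonzero scans"))
  if (is.null(rt_predicted))
    rt_predicted <- sum(rt * intensity) / sum(intensity)

  tss <- sum((intensity - mean(intensity))^2)
  best <- NULL; best_bic <- Inf; best_k <- 0L
  n <- length(rt)
  for (k in seq_len(max_components)) {
    fit <- .fit_ncomp(rt, intensity, k)
    if (is.null(fit)) next
    bic <- n * log(max(fit$rss, 1e-300) / n) + 3 * k * log(n)
    if (bic < best_bic) { best <- fit; best_bic <- bic; best_k <- k }
  }
  if (is.null(best)) return(invalid("optimizer non-convergence"))

  sel <- which.min(abs(best$mu - rt_predicted))
  bounds <- c(best$mu[sel] - 3 * best$sigma[sel],
              best$mu[sel] + 3 * best$sigma[sel])
  bounds <- c(max(bounds[1], min(rt)), min(bounds[2], max(rt)))
  structure(list(valid = TRUE, reason = NA_character_,
                 n_components = best_k, mu = best$mu, sigma = best$sigma,
                 A = best$A, selected = sel, bounds = bounds,
                 goodness = if (tss > 0) 1 - best$rss / tss else NA_real_),
            class = "elution_fit")
}
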