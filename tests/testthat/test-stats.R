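test_that("pure-null effects yield no significant records", {
  fit <- shrinkage_fit(rep(0, 200), rep(1e-3, 200))
  pi_hat <- attr(fit, "pi")
  expect_gt(pi_hat[1], 0.95)
  expect_equal(sum(fit$qvalue <= 0.01), 0)
})

test_that("a single strong effect among nulls is detected", {
  set.seed(5)
  effects <- c(rnorm(1000, 0, 0.01), 0.1)   # last record at 10 SEs
  se <- rep(0.01, 1001)
  fit <- shrinkage_fit(effects, se)
  expect_lt(fit$qvalue[1001], 0.01)
})

test_that("posterior means shrink toward zero", {
  set.seed(9)
  effects <- abs(rnorm(300, 0, 0.05))
  se <- runif(300, 0.005, 0.05)
  fit <- shrinkage_fit(effects, se)
  # aggregate shrinkage, and per-record shrinkage where the effect is
  # well resolved (the half-uniform prior can pull near-zero observations
  # upward, so the per-record inequality only holds away from zero)
  expect_lt(mean(abs(fit$posterior_mean)), mean(abs(fit$effect)))
  resolved <- effects >= 3 * se
  expect_true(all(fit$posterior_mean[resolved] <= fit$effect[resolved] + 1e-12))
  expect_true(all(fit$posterior_mean >= 0))
  expect_true(all(fit$qvalue >= 0 & fit$qvalue <= 1))
  # q-values are running means of sorted lfsr, hence monotone in lfsr order
  ord <- order(fit$lfsr)
  expect_true(all(diff(fit$qvalue[ord]) >= -1e-12))
})

test_that("shrinkage rejects nonpositive standard errors", {
  expect_error(shrinkage_fit(c(0, 1), c(0.1, 0)), "positive")
})

test_that("oxidation-prone flagging uses distances from the global median", {
  est <- data.frame(peptide = sprintf("P%03d", 1:80),
                    grouping = "interage",
                    mos_invivo = c(rep(0.045, 50), rnorm(20, 0.045, 0.002),
                                   rep(0.30, 10)),
                    sem = 0.01, nrmse = 0.05, n_valid = 24L, pass = TRUE)
  flags <- flag_oxidation_prone(est, q_threshold = 0.01)
  expect_equal(attr(flags, "global_median"),
               median(est$mos_invivo))
  high <- flags$peptide[flags$mos_invivo > 0.2]
  expect_true(all(flags$significant[flags$peptide %in% high]))
  low <- flags$significant[flags$mos_invivo < 0.1]
  expect_equal(sum(low), 0)

  # all-equal estimates: zero effects, nothing significant
  est0 <- est; est0$mos_invivo <- 0.05
  flags0 <- flag_oxidation_prone(est0)
  expect_equal(sum(flags0$significant), 0)
})

test_that("Holm adjustment matches the textbook step-down", {
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(rep(1, 5)), rep(1, 5))
  expect_error(holm_adjust(c(0.5, 1.2)), "0, 1")

  # brute-force step-down oracle on random vectors
  set.seed(13)
  for (i in 1:10) {
    p <- runif(sample(3:40, 1))
    m <- length(p)
    ord <- order(p)
    adj_sorted <- cummax(pmin(1, (m - seq_len(m) + 1) * p[ord]))
    oracle <- numeric(m); oracle[ord] <- adj_sorted
    expect_lt(max(abs(holm_adjust(p) - oracle)), 1e-12)
  }
})

test_that("age contrasts compute Welch t statistics from pooled SEMs", {
  mk <- function(mos, sem, n = 12L)
    data.frame(peptide = "AMSSK", grouping = "g", mos_invivo = mos,
               sem = sem, nrmse = 0.05, n_valid = n, pass = TRUE)
  same <- age_contrast(mk(0.1, 0.01), mk(0.1, 0.01))
  expect_equal(same$t, 0)
  expect_equal(same$pvalue, 1)

  diffd <- age_contrast(mk(0.10, 0.01), mk(0.15, 0.01))
  expect_equal(diffd$t, 0.05 / sqrt(2e-4), tolerance = 1e-4)
  expect_equal(diffd$effect, 0.05)
})

test_that("type-I error of the age contrast is calibrated on null data", {
  set.seed(17)
  t_design <- rep(c(0.10, 0.25), each = 6)
  n_pep <- 1000
  pvals <- sapply(seq_len(n_pep), function(i) {
    m_true <- 0.05
    fy <- fit_titration_response(t_design,
            t_design + (1 - t_design) * m_true + rnorm(12, 0, 0.01))
    fo <- fit_titration_response(t_design,
            t_design + (1 - t_design) * m_true + rnorm(12, 0, 0.01))
    young <- data.frame(peptide = "P", grouping = "young",
                        mos_invivo = fy$mos_invivo, sem = fy$sem,
                        nrmse = fy$nrmse, n_valid = 12L, pass = TRUE)
    old <- data.frame(peptide = "P", grouping = "old",
                      mos_invivo = fo$mos_invivo, sem = fo$sem,
                      nrmse = fo$nrmse, n_valid = 12L, pass = TRUE)
    age_contrast(young, old)$pvalue
  })
  frac <- mean(pvals <= 0.05)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
})

test_that("shrinkage calibration: few null false flags, strong effects found", {
  set.seed(29)
  n <- 500; n_null <- 450
  true_eff <- c(rep(0, n_null), runif(n - n_null, 0.05, 0.3))
  obs <- true_eff + rnorm(n, 0, 0.01)
  fit <- shrinkage_fit(obs, rep(0.01, n))
  flagged <- fit$qvalue <= 0.01
  expect_lte(mean(flagged[seq_len(n_null)]), 0.02)
  strong <- true_eff >= 0.1
  expect_gte(mean(flagged[strong]), 0.8)
})
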