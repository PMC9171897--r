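make_pq <- function(peptide, runs, mos = 0.1, valid = TRUE) {
  data.frame(peptide = peptide, run = runs, charge = 2L, slope = mos,
             r_squared = 0.99, ratio = mos / (1 - mos), mos = mos,
             n_points = 10L, valid = valid, reason = NA_character_,
             stringsAsFactors = FALSE)
}

test_that("peptide assembly enforces the per-group validity minimum", {
  des <- make_titration_design()
  young <- des$run[des$age_group == "young"]
  old <- des$run[des$age_group == "old"]

  # 7/12 valid in both groups: retained
  pq_keep <- rbind(make_pq("AMSSK", young[1:7]), make_pq("AMSSK", old[1:7]))
  # only 6/12 valid in young: excluded
  pq_drop <- rbind(make_pq("GMLLR", young[1:6]), make_pq("GMLLR", old[1:8]))
  out <- assemble_peptide_table(rbind(pq_keep, pq_drop), des, min_valid = 7)
  expect_true("AMSSK" %in% out$measurements$peptide)
  expect_false("GMLLR" %in% out$measurements$peptide)
  expect_equal(out$dropped$reason[out$dropped$peptide == "GMLLR"],
               "below min_valid")
})

test_that("cysteine-containing peptides are excluded regardless of counts", {
  des <- make_titration_design()
  pq <- rbind(make_pq("ACMK", des$run[des$age_group == "young"]),
              make_pq("ACMK", des$run[des$age_group == "old"]))
  out <- assemble_peptide_table(pq, des, min_valid = 7, drop_cysteine = TRUE)
  expect_equal(nrow(out$measurements), 0)
  expect_equal(out$dropped$reason, "cysteine-containing")

  out2 <- assemble_peptide_table(pq, des, min_valid = 7,
                                 drop_cysteine = FALSE)
  expect_equal(nrow(out2$measurements), 24)
})

test_that("a run absent from the design is rejected by name", {
  des <- make_titration_design()
  pq <- make_pq("AMSSK", c(des$run[1], "mystery_run"))
  expect_error(assemble_peptide_table(pq, des), "mystery_run")
})

test_that("titration fit solves the carrier-mixing model exactly", {
  # fully blocked peptide: measured MOS equals the carrier fraction
  fit0 <- fit_titration_response(t = rep(c(0.10, 0.25), each = 2),
                                 mos = rep(c(0.10, 0.25), each = 2))
  expect_equal(fit0$mos_invivo, 0, tolerance = 1e-8)
  expect_equal(fit0$nrmse, 0)
  expect_true(fit0$pass)

  # fully oxidized fixed point
  fit1 <- fit_titration_response(t = c(0.10, 0.10, 0.25, 0.25),
                                 mos = rep(1, 4))
  expect_equal(fit1$mos_invivo, 1, tolerance = 1e-8)

  expect_error(fit_titration_response(t = rep(0.1, 4), mos = rep(0.2, 4)),
               "degenerate")
  expect_error(fit_titration_response(t = c(0.1, 0.25), mos = c(0.1, 0.25)),
               "at least 3")
})

test_that("the fitted model at t = 0 is the in vivo estimate", {
  set.seed(3)
  t <- rep(c(0.10, 0.25), 6)
  mos <- t + (1 - t) * 0.2 + rnorm(12, 0, 0.01)
  fit <- fit_titration_response(t, mos)
  pred_t0 <- 0 + (1 - 0) * fit$mos_invivo
  expect_identical(pred_t0, fit$mos_invivo)

  # permutation invariance
  perm <- sample(12)
  fit_p <- fit_titration_response(t[perm], mos[perm])
  expect_equal(fit_p$mos_invivo, fit$mos_invivo, tolerance = 1e-10)
})

test_that("estimates are unbiased and SEMs calibrated (Monte Carlo)", {
  set.seed(101)
  t <- rep(c(0.10, 0.25), each = 6)
  reps <- replicate(500, {
    mos <- t + (1 - t) * 0.05 + rnorm(12, 0, 0.01)
    fit <- fit_titration_response(t, mos)
    c(fit$mos_invivo, fit$sem)
  })
  expect_lt(abs(mean(reps[1, ]) - 0.05), 0.005)
  ratio <- mean(reps[2, ]) / sd(reps[1, ])
  expect_gt(ratio, 0.7)
  expect_lt(ratio, 1.3)
})

test_that("parameter recovery is unbiased across the stoichiometry grid", {
  set.seed(202)
  t <- rep(c(0.10, 0.25), each = 6)
  for (m_true in c(0, 0.02, 0.05, 0.1, 0.3, 0.5)) {
    ests <- replicate(200, {
      mos <- t + (1 - t) * m_true + rnorm(12, 0, 0.01)
      fit_titration_response(t, mos)$mos_invivo
    })
    expect_lt(abs(mean(ests) - m_true), 0.005)
  }
})

test_that("the NRMSE gate is inclusive at the threshold", {
  # engineered residuals: NRMSE = RMSE / mean(mos)
  t <- c(0.1, 0.1, 0.25, 0.25)
  mos <- c(0.3, 0.1, 0.45, 0.25)  # noisy around m ~ 0.12
  fit <- fit_titration_response(t, mos, nrmse_threshold = 0.2)
  manual_rmse <- sqrt(mean((mos - (t + (1 - t) * fit$mos_invivo))^2))
  expect_equal(fit$nrmse, manual_rmse / mean(mos), tolerance = 1e-10)
  expect_identical(fit$pass, fit$nrmse <= 0.2)
  fit_at <- fit_titration_response(t, mos, nrmse_threshold = fit$nrmse)
  expect_true(fit_at$pass)
})
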