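test_that("elemental compositions follow residue chemistry", {
  g <- composition_from_sequence("G")
  expect_equal(g$counts, c(C = 2L, H = 5L, N = 1L, O = 2L, S = 0L))

  m_plain <- composition_from_sequence("M")
  m_ox <- composition_from_sequence("M", "mso16")
  expect_equal(m_ox$counts[["O"]], m_plain$counts[["O"]] + 1L)
  expect_equal(m_ox$label, "light16O")

  light <- composition_from_sequence("AMK", "mso16")
  heavy <- composition_from_sequence("AMK", "mso18")
  expect_equal(light$counts, heavy$counts)
  expect_false(light$label == heavy$label)
  expect_equal(heavy$monoisotopic_mass - light$monoisotopic_mass, 2.004246)

  expect_error(composition_from_sequence("AXZ"), "X")
  expect_error(composition_from_sequence("AMK", "phospho"), "phospho")
  expect_error(composition_from_sequence("AMK", c("mso16", "mso18")), "both")
  expect_error(composition_from_sequence("AMK", "cam_cys"), "cysteine")
})

test_that("single-atom envelope equals elemental abundances", {
  one_c <- structure(list(counts = c(C = 1L, H = 0L, N = 0L, O = 0L, S = 0L),
                          label = NA_character_, monoisotopic_mass = 12),
                     class = "elemental_composition")
  env <- isotope_envelope(one_c, K = 3)
  expect_equal(env$abundances[1], 0.9893, tolerance = 1e-10)
  expect_equal(env$abundances[2], 0.0107, tolerance = 1e-10)
  expect_error(isotope_envelope(one_c, K = 2), "at least 3")
})

test_that("envelopes are normalized probability vectors", {
  for (seqs in c("AMK", "GMFLLNDPEWILKQR", "WWWWMHHHK")) {
    env <- isotope_envelope(composition_from_sequence(seqs, "mso16"), K = 30)
    expect_true(all(env$abundances >= 0))
    expect_lte(sum(env$abundances), 1)
    expect_gte(sum(env$abundances), 1 - 1e-6)
  }
})

test_that("envelope matches the exhaustive polynomial-expansion oracle", {
  set.seed(42)
  for (i in 1:20) {
    comp <- random_composition()
    K <- sample(3:6, 1)
    env <- isotope_envelope(comp, K = K)
    expected <- oracle_envelope(comp$counts, K)
    expect_lt(sum(abs(env$abundances - expected)), 1e-8)
  }
})

test_that("a1/a0 never decreases with carbon count", {
  ratios <- sapply(1:40, function(nc) {
    comp <- structure(list(counts = c(C = nc, H = 10L, N = 2L, O = 3L, S = 1L),
                           label = NA_character_, monoisotopic_mass = 1),
                      class = "elemental_composition")
    a <- isotope_envelope(comp, K = 4)$abundances
    a[2] / a[1]
  })
  expect_true(all(diff(ratios) >= 0))
})

test_that("pair geometry places light and heavy isotopologues correctly", {
  env <- make_envelope(c(0.6, 0.3, 0.1), mass = 1000.0)
  geom <- pair_positions(env, charge = 2)
  expect_equal(geom$light_mz[1], (1000.0 + 2 * 1.00727646688) / 2)
  expect_equal(geom$heavy_mz[1] - geom$light_mz[1], 2.004246 / 2,
               tolerance = 1e-9)
  expect_equal(geom$light_mz[2] - geom$light_mz[1], 1.00335 / 2,
               tolerance = 1e-12)
  expect_equal(geom$heavy_mz - geom$light_mz,
               rep(2.004246 / 2, 3), tolerance = 1e-9)
  expect_error(pair_positions(env, 0), "positive")
  expect_error(pair_positions(env, -2), "positive")
})

test_that("mixing coefficients match the hand-convolved example", {
  env <- make_envelope(c(0.6, 0.3, 0.1))
  mc <- mixing_coefficients(env, light_channel = 0:1, heavy_channel = 2:4)
  expect_equal(mc$light_channel_weight_L, 0.9)
  expect_equal(mc$light_channel_weight_H, 0)
  expect_equal(mc$heavy_channel_weight_L, 0.1)
  expect_equal(mc$heavy_channel_weight_H, 1.0)
})

test_that("no envelope spillover means no off-diagonal mixing", {
  env <- make_envelope(c(0.7, 0.3, 0, 0, 0))
  mc <- mixing_coefficients(env, light_channel = 0:1, heavy_channel = 2:6)
  expect_equal(mc$heavy_channel_weight_L, 0)
  expect_equal(mc$light_channel_weight_H, 0)
})

test_that("mixing coefficients reproduce a brute-force forward model", {
  set.seed(7)
  for (i in 1:25) {
    a <- runif(sample(4:8, 1)); a <- a / sum(a)
    env <- make_envelope(a)
    K <- length(a) - 1L
    light_ch <- 0:sample(0:1, 1)
    heavy_ch <- setdiff(2:(K + 2L), light_ch)
    mc <- mixing_coefficients(env, light_ch, heavy_ch)
    L <- runif(1, 1, 100); H <- runif(1, 1, 100)
    fwd <- forward_channels(a, light_ch, heavy_ch, L, H)
    expect_lt(abs(fwd[["light"]] -
                    (mc$light_channel_weight_L * L +
                     mc$light_channel_weight_H * H)), 1e-12)
    expect_lt(abs(fwd[["heavy"]] -
                    (mc$heavy_channel_weight_L * L +
                     mc$heavy_channel_weight_H * H)), 1e-12)
  }
})

test_that("overlapping channel sets are rejected", {
  env <- make_envelope(c(0.6, 0.3, 0.1))
  expect_error(mixing_coefficients(env, 0:2, 2:4), "disjoint")
})
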