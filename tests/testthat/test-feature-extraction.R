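geom1 <- pair_positions(make_envelope(c(0.6, 0.3, 0.1), mass = 1000), 2)

test_that("extraction retrieves exact-match peaks and respects tolerance", {
  rt <- seq(10, 10.4, by = 0.1)
  target <- geom1$light_mz[1]
  pk <- data.frame(scan = 1:5, mz = target, intensity = c(10, 50, 100, 50, 10))
  ms1 <- build_ms1(rt, pk)
  ts <- extract_traces(ms1, geom1, rt_center = 10.2, rt_halfwidth = 1,
                       ppm_tol = 10)
  expect_true(ts$valid)
  expect_equal(ts$light[, 1], c(10, 50, 100, 50, 10))
  expect_equal(ts$light[, 2], rep(0, 5))

  # peak offset by twice the tolerance is excluded
  pk_off <- data.frame(scan = 1:5, mz = target * (1 + 20e-6), intensity = 100)
  ts_off <- extract_traces(build_ms1(rt, pk_off), geom1, 10.2, 1, ppm_tol = 10)
  expect_equal(ts_off$light[, 1], rep(0, 5))
})

test_that("the most intense of several in-tolerance peaks is taken", {
  rt <- seq(10, 10.4, by = 0.1)
  target <- geom1$light_mz[1]
  pk <- rbind(data.frame(scan = 1:5, mz = target * (1 - 4e-6), intensity = 30),
              data.frame(scan = 1:5, mz = target * (1 + 4e-6), intensity = 80))
  ts <- extract_traces(build_ms1(rt, pk), geom1, 10.2, 1, ppm_tol = 10)
  expect_equal(ts$light[, 1], rep(80, 5))
})

test_that("an empty extraction window is flagged invalid, not an error", {
  rt <- seq(10, 10.4, by = 0.1)
  pk <- data.frame(scan = 1, mz = 500, intensity = 1)
  ts <- extract_traces(build_ms1(rt, pk), geom1, rt_center = 50,
                       rt_halfwidth = 0.5)
  expect_false(ts$valid)
  expect_equal(nrow(ts$light), 0)
})

test_that("trace cosine is an inner-product similarity on the scan grid", {
  v <- c(1, 5, 9, 5, 1)
  expect_equal(trace_cosine(v, v), 1.0)
  expect_equal(trace_cosine(v, 3 * v), 1.0)
  expect_equal(trace_cosine(c(1, 0, 0), c(0, 1, 1)), 0.0)
  expect_equal(trace_cosine(v, rep(0, 5)), 0.0)
  expect_equal(trace_cosine(v, rev(v)), trace_cosine(rev(v), v))
  expect_error(trace_cosine(v, c(1, 2)), "scan grids")
})

test_that("cluster linking keeps the maximal prefix above threshold", {
  # 2-d columns with controlled adjacent cosines via rotations
  rot <- function(v, theta) c(cos(theta) * v[1] - sin(theta) * v[2],
                              sin(theta) * v[1] + cos(theta) * v[2])
  u <- c(1, 0)
  cols <- list(u)
  for (ang in acos(c(0.99, 0.95, 0.4, 0.97)))
    cols <- c(cols, list(rot(cols[[length(cols)]], ang)))
  m <- abs(do.call(cbind, cols))  # intensities nonnegative
  # cosines of |rotated| columns stay at the intended values in quadrant I
  cl <- link_cluster(m, threshold = 0.6)
  expect_equal(cl$kept, 0:2)
  expect_length(cl$cosines, 2)

  # inclusive threshold: adjacent cosines exactly 0.61 all pass at 0.6
  cols61 <- list(u)
  for (i in 1:3) cols61 <- c(cols61, list(rot(cols61[[i]], acos(0.61) *
                                                c(1, -1)[i %% 2 + 1])))
  m61 <- abs(do.call(cbind, cols61))
  cl61 <- link_cluster(m61, threshold = 0.6)
  expect_equal(cl61$kept, 0:3)

  # immediate break keeps only the monoisotopic trace
  m0 <- cbind(c(1, 0, 0), c(0, 1, 0))
  expect_equal(link_cluster(m0, 0.6)$kept, 0L)
})

test_that("elution fitting recovers a noiseless Gaussian", {
  rt <- seq(29.5, 30.5, length.out = 20)
  y <- 1e6 * exp(-(rt - 30.0)^2 / (2 * 0.1^2))
  fit <- fit_elution_profile(rt, y, rt_predicted = 30.0)
  expect_true(fit$valid)
  expect_equal(fit$n_components, 1L)
  expect_lt(abs(fit$mu[fit$selected] - 30.0), 0.01)
})

test_that("the component nearest the predicted RT is selected", {
  rt <- seq(10, 14, by = 0.05)
  y <- 1e6 * exp(-(rt - 11)^2 / (2 * 0.1^2)) +
       5e5 * exp(-(rt - 13)^2 / (2 * 0.1^2))
  fit <- fit_elution_profile(rt, y, max_components = 3, rt_predicted = 11)
  expect_true(fit$valid)
  expect_gte(fit$n_components, 2L)
  expect_lt(abs(fit$mu[fit$selected] - 11), 0.05)
})

test_that("elution-peak location is stable under multiplicative noise", {
  set.seed(11)
  rt <- seq(29, 31, length.out = 50)
  errs <- replicate(50, {
    y <- 1e6 * exp(-(rt - 30.0)^2 / (2 * 0.1^2)) * exp(rnorm(50, 0, 0.05))
    fit <- fit_elution_profile(rt, y, rt_predicted = 30.0)
    abs(fit$mu[fit$selected] - 30.0)
  })
  expect_lt(median(errs), 0.02)
})

test_that("too few nonzero scans yields an invalid fit with a reason", {
  fit <- fit_elution_profile(1:10, c(1, 2, 0, 0, 0, 0, 0, 0, 0, 0))
  expect_false(fit$valid)
  expect_match(fit$reason, "insufficient")
})
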