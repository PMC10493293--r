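test_that("parameter invariants are enforced", {
  expect_error(hrf_params(b = -1, p1 = 4.5, p2 = 7.9, V = 1.8), "b must be positive")
  expect_error(hrf_params(b = 0.9, p1 = 0.5, p2 = 7.9, V = 1.8), "p1 must exceed 1")
  expect_error(hrf_params(b = 0.9, p1 = 4.5, p2 = 4.0, V = 1.8), "must exceed p1")
  expect_error(hrf_params(b = 0.9, p1 = 4.5, p2 = 7.9, V = 0), "V must be positive")
  expect_error(hrf_params(A = 0, b = 0.9, p1 = 4.5, p2 = 7.9, V = 1.8), "nonzero")
  expect_error(evaluate_hrf(hrf_preset("mouse"), numeric(0)), "empty")
  expect_error(evaluate_hrf(hrf_preset("mouse"), c(1, 2)), "start at 0")
})

test_that("evaluation matches a log-gamma arithmetic oracle on random parameters", {
  withr::with_seed(11, {
    for (i in 1:20) {
      b <- runif(1, 0.2, 3); p1 <- runif(1, 1.5, 8)
      p2 <- p1 + runif(1, 0.5, 10); V <- runif(1, 0.3, 10)
      A <- runif(1, 0.1, 5)
      grid <- hrf_time_grid(30, 0.25)
      got <- evaluate_hrf(hrf_params(A, b, p1, p2, V), grid)$value
      want <- hrf_oracle_loggamma(grid, A, b, p1, p2, V)
      expect_equal(got, want, tolerance = 1e-12)
    }
  })
  expect_identical(evaluate_hrf(hrf_preset("mouse"))$value[1], 0)
})

test_that("mouse-preset curve has one sign change at the bisection root", {
  p <- hrf_preset("mouse")
  grid <- hrf_time_grid(30, 0.001)
  v <- evaluate_hrf(p, grid)$value
  signs <- sign(v[v != 0])
  expect_equal(sum(diff(signs) != 0), 1)

  ## bisection oracle on c1 t^(p1-1) = c2 t^(p2-1)
  c1 <- p$b^p$p1 / gamma(p$p1); c2 <- p$b^p$p2 / (p$V * gamma(p$p2))
  g <- function(t) c1 * t^(p$p1 - 1) - c2 * t^(p$p2 - 1)
  lo <- 1; hi <- 30
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (g(lo) * g(mid) <= 0) hi <- mid else lo <- mid
  }
  root <- (lo + hi) / 2
  crossing_idx <- which(diff(sign(v[v != 0])) != 0)[1]
  t_cross <- grid[v != 0][crossing_idx]
  expect_equal(t_cross, root, tolerance = 0.01)
})

test_that("human-preset peak location matches a dense-grid argmax oracle", {
  grid <- hrf_time_grid(32, 0.001)
  v <- evaluate_hrf(hrf_preset("human"), grid)$value
  ## oracle: direct argmax of the closed form on the same dense grid
  oracle <- hrf_oracle_loggamma(grid, 1, 1, 6, 16, 6)
  expect_equal(grid[which.max(v)], grid[which.max(oracle)])
  expect_equal(grid[which.max(v)], 5, tolerance = 0.01)
})

test_that("derivative curves vanish in the tail and converge to the analytic derivative", {
  p <- hrf_preset("mouse")
  grid <- hrf_time_grid(60, 0.05)
  dv <- hrf_basis_derivatives(p, grid)
  tail_idx <- grid > 50
  expect_lt(max(abs(dv$temporal$value[tail_idx])), 1e-6)
  expect_lt(max(abs(dv$dispersion$value[tail_idx])), 1e-6)

  ## analytic d/dt of A e^{-bt}(c1 t^{q1} - c2 t^{q2})
  c1 <- p$b^p$p1 / gamma(p$p1); c2 <- p$b^p$p2 / (p$V * gamma(p$p2))
  q1 <- p$p1 - 1; q2 <- p$p2 - 1
  tpos <- grid[grid > 0.5 & grid < 30]
  analytic <- -p$b * exp(-p$b * tpos) * (c1 * tpos^q1 - c2 * tpos^q2) +
    exp(-p$b * tpos) * (c1 * q1 * tpos^(q1 - 1) - c2 * q2 * tpos^(q2 - 1))
  idx <- match(tpos, grid)
  err_coarse <- max(abs(dv$temporal$value[idx] - analytic))
  dv_fine <- hrf_basis_derivatives(p, grid, shift = 0.001)
  err_fine <- max(abs(dv_fine$temporal$value[idx] - analytic))
  expect_lt(err_coarse, 0.05 * max(abs(analytic)))  # O(shift) backward difference
  expect_lt(err_fine, err_coarse / 10)  # finite difference converges
})

test_that("curve characterization reproduces the human 5.3 s FWHM and is scale invariant", {
  curve <- evaluate_hrf(hrf_preset("human"), hrf_time_grid(32, 0.01))
  s <- characterize_hrf(curve)
  expect_equal(round(s$fwhm, 1), 5.3)
  expect_lt(s$time_to_peak, s$time_to_undershoot)
  expect_lte(s$undershoot_value, 0)

  scaled <- hrf_curve(curve$time, curve$value * 10)
  s10 <- characterize_hrf(scaled)
  expect_equal(s10$time_to_peak, s$time_to_peak)
  expect_equal(s10$fwhm, s$fwhm)
  expect_equal(s10$time_to_undershoot, s$time_to_undershoot)
})

test_that("FWHM matches a brute-force half-max scan for a near-single-gamma curve", {
  p <- hrf_params(b = 1, p1 = 6, p2 = 16, V = 1e6)  # undershoot negligible
  s <- characterize_hrf(evaluate_hrf(p, hrf_time_grid(32, 0.01)))
  grid <- hrf_time_grid(32, 0.001)
  v <- hrf_oracle_loggamma(grid, 1, 1, 6, 16, 1e6)
  above <- grid[v >= max(v) / 2]
  brute <- max(above) - min(above)
  expect_equal(s$fwhm, brute, tolerance = 0.003)
})

test_that("normalization to maximum is exact, idempotent and peak-preserving", {
  curve <- evaluate_hrf(hrf_preset("mouse"))
  half <- hrf_curve(curve$time, curve$value * 0.5 / max(curve$value))
  n1 <- normalize_to_max(half)
  expect_equal(max(n1$value), 1)
  expect_equal(n1$value, half$value * 2)
  expect_equal(normalize_to_max(n1)$value, n1$value)
  expect_equal(which.max(n1$value), which.max(curve$value))
  expect_error(normalize_to_max(hrf_curve(0:3, c(0, -1, -2, -1))), "non-positive")
})

test_that("HRF parameter files round-trip through JSON", {
  p <- hrf_preset("mouse")
  tf <- tempfile(fileext = ".json")
  write_hrf_params(p, tf, source = "unit test")
  q <- read_hrf_params(tf)
  expect_equal(q[c("A", "b", "p1", "p2", "V")], p[c("A", "b", "p1", "p2", "V")])
  expect_equal(q$species, "mouse")
})

test_that("jittered curve sampling is deterministic and respects invariants", {
  m1 <- sample_hrf_curves(5, seed = 7)
  m2 <- sample_hrf_curves(5, seed = 7)
  expect_identical(m1, m2)
  expect_equal(dim(m1), c(5, length(hrf_time_grid())))
  expect_true(all(m1[, 1] == 0))
})
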