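test_that("boxcar carries the right stimulation mass and rejects bad dt", {
  pd <- block_paradigm()
  s <- boxcar(pd, dt = 0.1)
  expect_equal(sum(s$value) * s$dt, 20 * 10)
  one <- boxcar(block_paradigm(n_blocks = 1), dt = 0.1)
  runs <- rle(one$value)
  expect_equal(sum(runs$values == 1), 1)           # a single rectangle
  expect_equal(runs$lengths[runs$values == 1] * 0.1, 10)
  expect_error(boxcar(pd, dt = 0.3), "divide TR")

  ## near-impulse blocks: one short rectangle per block
  imp <- boxcar(block_paradigm(n_blocks = 5, stim_duration = 0.1,
                               rest_duration = 29.9), dt = 0.1)
  expect_equal(sum(rle(imp$value)$values == 1), 5)
})

test_that("pulse-level stimulus respects the duty cycle", {
  pd <- block_paradigm(n_blocks = 2)
  s <- boxcar(pd, dt = 0.05, pulse_level = TRUE)
  ## 10 pulses of 0.5 s per 10 s block
  expect_equal(sum(s$value) * s$dt, 2 * 10 * 0.5)
  expect_error(block_paradigm(pulse_frequency = 4, pulse_duration = 0.5),
               "duty cycle")
})

test_that("convolution matches a brute-force double sum and is linear", {
  pd <- block_paradigm(n_blocks = 2, stim_duration = 2, rest_duration = 4,
                       pre_window = 2)
  s <- boxcar(pd, dt = 0.5)
  h <- evaluate_hrf(hrf_preset("mouse"), hrf_time_grid(10, 0.5))

  ## brute-force: c[k] = dt * sum_j s[j] h[k-j+1]
  brute <- sapply(seq_along(s$value), function(k) {
    j <- seq_len(k)
    keep <- (k - j + 1) <= length(h$value)
    0.5 * sum(s$value[j[keep]] * h$value[k - j[keep] + 1])
  })
  got_fine <- hrfkit:::fft_convolve(s$value, h$value, dt = 0.5)
  expect_equal(got_fine, brute, tolerance = 1e-10)

  reg <- convolve_with_hrf(s, h, TR = 1)
  ## sampling picks every TR/dt-th fine sample
  expect_equal(reg, got_fine[seq(1, length(got_fine), by = 2)][seq_along(reg)])

  ## linearity: conv(a*s1 + s2) = a conv(s1) + conv(s2)
  s2 <- s; s2$value <- rev(s$value)
  mix <- s; mix$value <- 3 * s$value + s2$value
  expect_equal(convolve_with_hrf(mix, h, TR = 1),
               3 * convolve_with_hrf(s, h, TR = 1) + convolve_with_hrf(s2, h, TR = 1),
               tolerance = 1e-10)

  ## zero stimulus and impulse identities
  z <- s; z$value <- 0 * z$value
  expect_equal(convolve_with_hrf(z, h, TR = 1), rep(0, length(reg)))
  imp <- s; imp$value <- c(1 / 0.5, rep(0, length(s$value) - 1))
  expect_equal(convolve_with_hrf(imp, h, TR = 1)[1:6], h$value[seq(1, 11, by = 2)])
})

test_that("canonical designs have the stated task columns and full rank", {
  pd <- block_paradigm()
  d1 <- build_canonical_design(pd, hrf_preset("mouse"))
  expect_equal(length(attr(d1, "task_cols")), 1)
  expect_equal(nrow(d1), 600)
  d3 <- build_canonical_design(pd, hrf_preset("mouse"), order = 3)
  expect_equal(length(attr(d3, "task_cols")), 3)
  expect_equal(colnames(d3)[1:3], c("task", "task_tderiv", "task_ddisp"))
  expect_equal(qr(d3)$rank, ncol(d3))
  expect_error(build_canonical_design(pd, hrf_preset("mouse"), order = 2), "order")

  ## bit-exact reproducibility
  expect_identical(d3, build_canonical_design(pd, hrf_preset("mouse"), order = 3))
})

test_that("FIR design tiles the block window", {
  pd <- block_paradigm()
  X <- build_fir_design(pd, order = 9, window = 30)
  expect_equal(length(attr(X, "task_cols")), 9)
  expect_equal(nrow(X), 600)
  ## each bin collects about 20 blocks x (30/9) s / TR volumes
  sums <- colSums(X[, 1:9])
  ## late bins of the final block fall past the last analyzed volume
  expect_true(all(sums >= 19 * 3 & sums <= 20 * 4))
  expect_equal(sum(sums), 20 * 30 - 10)  # all volumes from t=10 on, minus truncation
  ## a volume inside exactly one block window has exactly one FIR entry
  expect_true(all(rowSums(X[, 1:9]) <= 1))
  inwin <- rowSums(X[, 1:9]) == 1
  expect_equal(sum(inwin), 590)

  ## FIR columns are mutually orthogonal when cycles do not overlap
  G <- crossprod(X[, 1:9])
  expect_equal(G - diag(diag(G)), matrix(0, 9, 9), ignore_attr = TRUE)

  ## order 1 reduces to a shifted boxcar covering the whole window
  X1 <- build_fir_design(pd, order = 1, window = 10)
  stim_on <- rep(FALSE, 600)
  for (o in block_onsets(pd, 20) - 20) stim_on[(o + 1):(o + 10)] <- TRUE
  expect_equal(as.numeric(X1[, 1]), as.numeric(stim_on))

  expect_error(build_fir_design(pd, order = 40, window = 30), "below the TR")
})

test_that("events tables round-trip and match block onsets", {
  pd <- block_paradigm()
  tf <- tempfile(fileext = ".tsv")
  write_events(pd, tf, n_discard = 20)
  ev <- read_events(tf)
  expect_equal(ev$onset, 30 + (0:19) * 30)
  expect_equal(ev$duration, rep(10, 20))
  tf2 <- tempfile(fileext = ".tsv")
  write_design(build_canonical_design(pd, hrf_preset("mouse")), tf2)
  d <- hrfkit:::read_tsv(tf2)
  expect_equal(names(d), c("task", "intercept"))
  expect_equal(nrow(d), 600)
})
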