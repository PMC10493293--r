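test_that("time-course extraction is the mask-structure intersection", {
  labels <- array(0L, c(4, 4, 2))
  labels[1:2, 1, 1] <- 1L; labels[3:4, 1, 1] <- 2L
  data4d <- array(seq_len(4 * 4 * 2 * 3), c(4, 4, 2, 3))
  mask_all <- labels > 0L
  tc <- extract_voxel_timecourses(data4d, labels, mask_all)
  expect_named(tc, c("1", "2"))
  expect_equal(ncol(tc[["1"]]), 2)

  mask_partial <- array(FALSE, c(4, 4, 2)); mask_partial[2:3, 1, 1] <- TRUE
  tc2 <- extract_voxel_timecourses(data4d, labels, mask_partial)
  expect_equal(ncol(tc2[["1"]]), 1)
  expect_equal(ncol(tc2[["2"]]), 1)
  expect_equal(attr(tc2[["1"]], "voxels"), 2L)
  ## values come from the right voxel
  expect_equal(as.numeric(tc2[["1"]][, 1]), data4d[2, 1, 1, ])

  mask_out <- array(FALSE, c(4, 4, 2)); mask_out[1, 4, 2] <- TRUE
  expect_length(extract_voxel_timecourses(data4d, labels, mask_out), 0)
})

test_that("moving-average smoothing is exact on constants, identity windows and ramps", {
  x <- rep(3.5, 20)
  expect_equal(smooth_temporal(x, 5, 1), x)
  y <- rnorm(20)
  expect_equal(smooth_temporal(y, 1, 1), y)      # window = TR -> identity
  ramp <- seq(0, 19)
  sm <- smooth_temporal(ramp, 5, 1)
  expect_equal(sm[3:18], ramp[3:18])             # linear is invariant inside
  ## hand value at an interior point with window 5
  z <- c(1, 4, 2, 8, 5, 7)
  expect_equal(smooth_temporal(z, 5, 1)[3], mean(z[1:5]))
  ## matrix input smooths per column
  m <- cbind(ramp, rep(1, 20))
  expect_equal(smooth_temporal(m, 5, 1)[, 2], rep(1, 20))
})

test_that("epoch averaging folds cycles and normalizes to the pre-onset baseline", {
  pd <- block_paradigm(n_blocks = 2, stim_duration = 2, rest_duration = 4,
                       TR = 1, pre_window = 2)
  ## two 6 s cycles; baseline level 100, known per-bin values
  c1 <- c(100, 102, 104, 106, 104, 102)
  c2 <- c(100, 104, 106, 108, 106, 104)
  ec <- epoch_average(c(c1, c2), pd)
  manual <- (c1 + c2) / 2
  base <- mean(manual[1:2])
  expect_equal(ec$value, 100 * (manual - base) / base)
  expect_equal(mean(ec$value[1:2]), 0)   # baseline mean zero
  expect_equal(ec$time, 0:5)
  expect_equal(ec$n_cycles, 2)
  expect_error(epoch_average(c1, pd), "at least 2 complete cycles")

  ## pure-baseline series maps to the zero curve
  flat <- epoch_average(rep(100, 12), pd)
  expect_equal(flat$value, rep(0, 6))
})

test_that("noise-free generated voxels epoch-average to the scaled regressor", {
  spec <- synthetic_spec(dims = c(12, 12, 6), n_structures = 4, noise_sd = 0,
                         response_amplitude_mean = 0.8,
                         response_amplitude_sd = 0, seed = 5)
  ds <- generate_dataset(spec)
  pos <- ds$truth$voxel[ds$truth$class == "positive"]
  flat <- matrix(ds$data, ncol = spec$n_volumes)
  series <- flat[pos[1], (spec$n_discard + 1):spec$n_volumes]
  ec <- epoch_average(series, ds$paradigm)
  ## expected: % conversion of baseline + amplitude * folded regressor
  reg_an <- ds$regressor[(spec$n_discard + 1):spec$n_volumes]
  fold <- rowMeans(matrix(reg_an, nrow = 30))
  raw <- 100 + 0.8 * fold
  expected <- 100 * (raw - mean(raw[1:10])) / mean(raw[1:10])
  expect_equal(ec$value, expected, tolerance = 1e-12)
  ## the pre-onset baseline sits in the previous block's undershoot, so the
  ## measured peak slightly exceeds the generating amplitude
  expect_gte(max(ec$value), 0.8)
  expect_lt(max(ec$value), 0.9)
})

test_that("polarity criteria follow the amplitude and decay rules", {
  rise <- function(peak, post_min) {
    v <- c(rep(0, 10), seq(0, peak, length.out = 8),
           seq(peak, post_min, length.out = 8), rep(post_min, 4))
    make_epoch(v)
  }
  expect_equal(classify_polarity(rise(0.5, 0.1)), "unclassified")  # below 0.6%
  expect_equal(classify_polarity(rise(1.0, 0.7)), "unclassified")  # only 30% decay
  expect_equal(classify_polarity(rise(1.0, 0.5)), "positive")      # 50% decay
  expect_equal(classify_polarity(rise(0.6, 0.0)), "positive")      # boundary amplitude
  neg <- rise(1.0, 0.4); neg$value <- -neg$value
  expect_equal(classify_polarity(neg), "negative")
  flat <- make_epoch(rep(0, 30))
  expect_equal(classify_polarity(flat), "unclassified")
})

test_that("full noise-free chain classifies exactly the truth responders", {
  spec <- synthetic_spec(dims = c(12, 12, 6), n_structures = 4, noise_sd = 0,
                         response_amplitude_mean = 0.8,
                         response_amplitude_sd = 0, negative_fraction = 0.03,
                         seed = 6)
  ds <- generate_dataset(spec)
  flat <- matrix(ds$data, ncol = spec$n_volumes)
  an <- (spec$n_discard + 1):spec$n_volumes
  got <- vapply(seq_len(nrow(ds$truth)), function(i) {
    series <- smooth_temporal(flat[ds$truth$voxel[i], an], 5, 1)
    classify_polarity(epoch_average(series, ds$paradigm))
  }, character(1))
  expected <- ifelse(ds$truth$class == "none", "unclassified", ds$truth$class)
  expect_equal(got, expected, ignore_attr = TRUE)
})

test_that("structure means require more than four voxels", {
  curves4 <- replicate(4, mouse_epoch_curve(), simplify = FALSE)
  expect_null(structure_mean_curve(curves4))
  curves5 <- replicate(5, mouse_epoch_curve(), simplify = FALSE)
  mc <- structure_mean_curve(curves5, structure = "SC")
  expect_s3_class(mc, "epoch_curve")
  expect_equal(mc$n_voxels, 5)
  expect_equal(mc$value, curves5[[1]]$value)   # identical curves: mean = input
})
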