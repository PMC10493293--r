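test_that("NMSE follows its definition on toy pairs", {
  x <- c(1, 2, 4)
  expect_equal(compute_nmse(x, x), 0)
  expect_equal(compute_nmse(x, rep(mean(x), 3)), 1)
  ## hand arithmetic: residuals (1, -1, 0.5), var = mean((x - 7/3)^2)
  f <- c(0, 3, 3.5)
  expect_equal(compute_nmse(x, f),
               mean(c(1, 1, 0.25)) / mean((x - mean(x))^2))
  expect_error(compute_nmse(rep(2, 3), c(1, 2, 3)), "zero variance")
  expect_error(compute_nmse(x, c(1, 2)), "share the grid")
})

test_that("onset detection finds the 10%-of-peak crossing", {
  tt <- seq(0, 30, by = 0.5)
  step <- ifelse(tt >= 12, 1, 0)
  expect_equal(detect_onset(tt, step), 12)
  early <- pmax(0, tt - 8) * exp(-(tt - 8) / 4)
  expect_lt(detect_onset(tt, early), 10)
  late <- pmax(0, tt - 10.5)
  expect_gte(detect_onset(tt, late), 10)
  expect_error(detect_onset(tt, -step), "no positive peak")
})

test_that("noise-free epoch curves refit to the generating parameters", {
  pd <- block_paradigm()
  curve <- mouse_epoch_curve(amplitude = 0.84)
  fit <- fit_hrf(curve, pd, seed = 0)
  expect_true(fit$converged)
  expect_true(fit$included)
  expect_equal(fit$params$b, 0.9, tolerance = 0.02)
  expect_equal(fit$params$p1, 4.5, tolerance = 0.02)
  expect_equal(fit$params$p2, 7.9, tolerance = 0.02)
  expect_equal(fit$params$V, 1.8, tolerance = 0.02)
  expect_lt(fit$nmse, 1e-6)
  expect_gte(fit$onset, 10)

  ## human-preset curve
  pred <- epoch_predictor(pd)
  hp <- hrf_preset("human")
  vals <- pred(c(1, hp$b, hp$p1, hp$p2 - hp$p1, hp$V))
  fith <- fit_hrf(make_epoch(vals), pd, seed = 0)
  expect_equal(fith$params$p1, 6, tolerance = 0.02)

  ## refitting a fit's own prediction gives zero NMSE
  refit <- fit_hrf(make_epoch(fit$fitted), pd, seed = 1)
  expect_lt(refit$nmse, 1e-8)
})

test_that("parameter recovery degrades gracefully under acquisition noise", {
  pd <- block_paradigm()
  pred <- epoch_predictor(pd)
  truth <- c(A = 0.84, b = 0.9, p1 = 4.5, dp = 3.4, V = 1.8)
  clean <- pred(truth)
  peak <- max(clean)
  ## structure curves under study conditions: per-volume noise at 10% of the
  ## response amplitude, folded over 20 paradigm cycles and averaged over the
  ## minimum 5 voxels a structure must contribute
  sd_epoch <- 0.1 * peak / sqrt(20 * 5)
  rel_err <- matrix(NA_real_, 50, 4)
  withr::with_seed(21, {
    for (i in 1:50) {
      noisy <- clean + rnorm(length(clean), 0, sd_epoch)
      f <- fit_hrf(make_epoch(noisy), pd, seed = i, predictor = pred)
      if (f$converged)
        rel_err[i, ] <- abs(c(f$params$b, f$params$p1, f$params$p2, f$params$V) /
                              c(0.9, 4.5, 7.9, 1.8) - 1)
    }
  })
  expect_gt(mean(!is.na(rel_err[, 1])), 0.9)
  med <- apply(rel_err, 2, stats::median, na.rm = TRUE)
  ## peak-shape parameters are well identified by the block response
  expect_lte(med[1], 0.15)  # b
  expect_lte(med[2], 0.15)  # p1
  ## the small undershoot constrains p2 and V only weakly on this design;
  ## their errors stay bounded but above the peak-parameter level
  expect_lte(med[3], 0.5)
  expect_lte(med[4], 0.5)
})

test_that("QC inclusion is monotone in the NMSE threshold", {
  pd <- block_paradigm()
  pred <- epoch_predictor(pd)
  clean <- pred(c(0.84, 0.9, 4.5, 3.4, 1.8))
  withr::with_seed(3, {
    fits <- lapply(c(0, 0.05, 0.3, 0.8), function(ns)
      fit_hrf(make_epoch(clean + rnorm(length(clean), 0, ns)), pd,
              seed = 5, predictor = pred))
  })
  inc_strict <- vapply(fits, function(f)
    f$converged && f$nmse <= 0.05 && f$onset >= 10, logical(1))
  inc_loose <- vapply(fits, function(f)
    f$converged && f$nmse <= 0.1 && f$onset >= 10, logical(1))
  expect_true(all(!inc_strict | inc_loose))  # strict set is a subset
  expect_true(any(!inc_loose))               # the noisiest curve fails QC
})

test_that("poor fits and pre-stimulus onsets are excluded by QC", {
  pd <- block_paradigm()
  ## structureless curve: best fit explains almost nothing
  withr::with_seed(12, junk <- make_epoch(rnorm(30, 0, 0.5)))
  fjunk <- fit_hrf(junk, pd, seed = 2)
  if (fjunk$converged) {
    expect_gt(fjunk$nmse, 0.1)
    expect_false(fjunk$included)
  } else {
    expect_false(fjunk$included)
  }

  ## a response rising before the stimulation onset: generated with an
  ## earlier onset than the analysis paradigm assumes
  early_pd <- block_paradigm(pre_window = 6)
  pred_early <- epoch_predictor(early_pd)
  early_curve <- pred_early(c(0.84, 0.9, 4.5, 3.4, 1.8))
  fearly <- fit_hrf(make_epoch(early_curve), early_pd, seed = 2, onset_min = 10)
  expect_true(fearly$converged)
  expect_lt(fearly$onset, 10)
  expect_false(fearly$included)
})

test_that("whole-brain aggregation refits the shared shape", {
  pd <- block_paradigm()
  pred <- epoch_predictor(pd)
  mk_fit <- function(amp) fit_hrf(make_epoch(amp * pred(c(1, 0.9, 4.5, 3.4, 1.8)) /
                                               max(pred(c(1, 0.9, 4.5, 3.4, 1.8)))),
                                  pd, seed = 3, predictor = pred)
  f1 <- mk_fit(0.8)
  agg1 <- aggregate_whole_brain(list(f1, f1, f1))
  expect_equal(max(agg1$curve$value), 1)
  expect_equal(agg1$params$b, f1$params$b, tolerance = 0.01)
  expect_equal(agg1$params$p1, f1$params$p1, tolerance = 0.01)

  ## amplitude-scaled copies aggregate like a single input
  f2 <- mk_fit(1.6)
  agg2 <- aggregate_whole_brain(list(f1, f2))
  expect_equal(agg2$curve$value, agg1$curve$value, tolerance = 1e-6)
  expect_equal(agg2$n, 2)

  expect_error(aggregate_whole_brain(list()), "no included fits")
})
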