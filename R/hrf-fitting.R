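#' Forward model: predicted epoch response of an HRF under a block paradigm
#'
#' Builds a predictor closure mapping HRF parameters to the epoch-averaged,
#' baseline-subtracted response a voxel driven by that HRF would show: the
#' HRF is convolved with the block stimulus over the full acquisition,
#' sampled at the volume times, the discarded lead-in dropped, and the series
#' folded into one cycle exactly as [epoch_average()] folds measured data.
#' The stimulus transform is cached, so repeated evaluation inside the
#' optimizer is cheap.
#'
#' @param paradigm a [block_paradigm()].
#' @param n_volumes,n_discard acquisition geometry.
#' @param dt fine convolution grid spacing (s).
#' @return Function `f(par, fine = FALSE)` taking `par = c(A, b, p1, dp, V)`
#'   with `p2 = p1 + dp`, returning the predicted epoch curve values at TR
#'   resolution (or at `dt` resolution when `fine = TRUE`).
#' @export
epoch_predictor <- function(paradigm, n_volumes = 620, n_discard = 20, dt = 0.05) {
  TR <- paradigm$TR
  stim <- boxcar(paradigm, dt = dt, total_time = n_volumes * TR,
                 n_discard = n_discard)
  hgrid <- hrf_time_grid(30, dt)
  nh <- length(hgrid)
  n <- length(stim$value) + nh - 1L
  nf <- stats::nextn(n, 2)
  Bf <- stats::fft(c(stim$value, rep(0, nf - length(stim$value))))
  n_cycle <- round(cycle_length(paradigm) / TR)
  n_base <- round(paradigm$pre_window / TR)
  per_s <- round(1 / dt)
  n_cycle_fine <- round(cycle_length(paradigm) / dt)
  n_an <- n_volumes - n_discard
  n_full <- floor(n_an / n_cycle)
  function(par, fine = FALSE) {
    h <- hrf_eval_raw(hgrid, par[1], par[2], par[3], par[3] + par[4], par[5])
    conv <- Re(stats::fft(Bf * stats::fft(c(h, rep(0, nf - nh))),
                          inverse = TRUE))[seq_along(stim$value)] / nf * dt
    if (fine) {
      i0 <- round(n_discard * TR / dt) + 1L
      seg <- conv[i0:(i0 + n_full * n_cycle_fine - 1L)]
      ep <- rowMeans(matrix(seg, nrow = n_cycle_fine))
      base <- mean(ep[seq_len(round(paradigm$pre_window / dt))])
      return(ep - base)
    }
    sig <- conv[round((seq_len(n_volumes) - 1) * TR / dt) + 1L]
    sig <- sig[(n_discard + 1):n_volumes]
    ep <- rowMeans(matrix(sig[seq_len(n_full * n_cycle)], nrow = n_cycle))
    ep - mean(ep[seq_len(n_base)])
  }
}

#' Normalized mean squared error of a fit
#'
#' Mean squared residual divided by the (population) variance of the measured
#' curve, so a fit no better than the curve's mean scores 1.
#'
#' @param observed,fitted numeric vectors on the same grid.
#' @return Dimensionless NMSE.
#' @export
compute_nmse <- function(observed, fitted) {
  if (length(observed) != length(fitted)) stopf("curves must share the grid")
  v <- mean((observed - mean(observed))^2)
  if (v == 0) stopf("degenerate input: observed curve has zero variance")
  mean((observed - fitted)^2) / v
}

#' Response onset of a fitted curve
#'
#' First time at which the fitted response exceeds 10% of its (positive)
#' peak. Used for quality control: a fitted response that rises before the
#' stimulation onset (onset < pre-onset baseline, 10 s here) is excluded.
#'
#' @param time,value the fitted curve.
#' @param frac onset threshold as a fraction of the peak.
#' @return Onset time (s).
#' @export
detect_onset <- function(time, value, frac = 0.1) {
  pk <- max(value)
  if (pk <= 0) stopf("degenerate curve: no positive peak")
  idx <- which(value > frac * pk)
  time[idx[1]]
}

default_hrf_bounds <- function() {
  list(lower = c(A = 1e-4, b = 0.1, p1 = 1.5, dp = 0.5, V = 0.2),
       upper = c(A = 1e3, b = 5, p1 = 15, dp = 25, V = 20))
}

#' Fit the two-gamma HRF to a structure epoch curve
#'
#' Least-squares fit of `A * (HRF(b, p1, p2, V) convolved with the paradigm,
#' epoch-averaged)` to a measured epoch curve, by bounded Levenberg-Marquardt
#' with multi-start initialization (random log-scale jitter around the
#' initial point, fixed seed). The undershoot shape is parameterized as
#' `p2 = p1 + dp` with `dp > 0`, so the constraint `p2 > p1` is a box bound.
#' Quality control marks a fit `included` when it converged, its NMSE is at
#' most `nmse_max` and its onset is not earlier than the stimulation onset.
#'
#' @param curve an [epoch_average()] curve (or list with `time`, `value`).
#' @param paradigm a [block_paradigm()].
#' @param init center of the multi-start cloud, named `(b, p1, p2, V)`.
#' @param bounds list with `lower`/`upper` vectors over `(A, b, p1, dp, V)`.
#' @param n_starts number of optimizer starts.
#' @param seed RNG seed for the start cloud.
#' @param nmse_max NMSE inclusion threshold.
#' @param onset_min earliest acceptable onset (s); defaults to the paradigm's
#'   pre-onset window (stimulation onset).
#' @param n_volumes,n_discard acquisition geometry the epoch curve came from.
#' @param predictor optionally a precomputed [epoch_predictor()] (reused
#'   across many fits for speed).
#' @return An object of class `hrf_fit`: `params` (an [hrf_params()]),
#'   `nmse`, `onset` (s), `converged`, `included`, `fitted` values on the
#'   curve grid, and `deviance`.
#' @export
fit_hrf <- function(curve, paradigm = block_paradigm(),
                    init = c(b = 1, p1 = 5, p2 = 10, V = 2),
                    bounds = default_hrf_bounds(), n_starts = 8, seed = 1,
                    nmse_max = 0.1, onset_min = NULL,
                    n_volumes = 620, n_discard = 20, predictor = NULL) {
  y <- curve$value
  pred <- predictor %||% epoch_predictor(paradigm, n_volumes, n_discard)
  onset_min <- onset_min %||% paradigm$pre_window
  scale0 <- max(abs(y))
  if (scale0 == 0) stopf("degenerate input: flat curve")
  center <- c(A = scale0 * 3, b = unname(init["b"]), p1 = unname(init["p1"]),
              dp = unname(init["p2"] - init["p1"]), V = unname(init["V"]))
  lo <- bounds$lower; up <- bounds$upper
  best <- NULL
  withr::with_seed(seed, {
    for (s in seq_len(n_starts)) {
      start <- center * exp(stats::runif(5, -0.5, 0.5))
      start <- pmin(pmax(start, lo), up)
      fit <- tryCatch(
        minpack.lm::nls.lm(start, lower = lo, upper = up,
                           fn = function(p) pred(p) - y,
                           control = minpack.lm::nls.lm.control(maxiter = 300)),
        error = function(e) NULL)
      if (!is.null(fit) && fit$info %in% 1:4 &&
          (is.null(best) || fit$deviance < best$deviance)) best <- fit
    }
  })
  if (is.null(best)) {
    return(structure(list(params = NULL, nmse = Inf, onset = NA_real_,
                          converged = FALSE, included = FALSE,
                          fitted = NULL, deviance = Inf), class = "hrf_fit"))
  }
  par <- stats::coef(best)
  params <- hrf_params(A = par[["A"]], b = par[["b"]], p1 = par[["p1"]],
                       p2 = par[["p1"]] + par[["dp"]], V = par[["V"]])
  fitted_vals <- pred(par)
  nmse <- compute_nmse(y, fitted_vals)
  fine <- pred(par, fine = TRUE)
  t_fine <- seq(0, by = 0.05, length.out = length(fine))
  onset <- if (max(fine) > 0) detect_onset(t_fine, fine) else NA_real_
  included <- !is.na(onset) && nmse <= nmse_max && onset >= onset_min
  structure(list(params = params, nmse = nmse, onset = onset,
                 converged = TRUE, included = included,
                 fitted = fitted_vals, deviance = best$deviance),
            class = "hrf_fit")
}

#' @export
print.hrf_fit <- function(x, ...) {
  if (!x$converged) {
    cat("HRF fit: did not converge\n")
    return(invisible(x))
  }
  cat(sprintf("HRF fit: b = %.3g, p1 = %.3g, p2 = %.3g, V = %.3g\n",
              x$params$b, x$params$p1, x$params$p2, x$params$V))
  cat(sprintf("  NMSE %.4g, onset %.2f s, %s\n", x$nmse, x$onset,
              if (x$included) "included" else "excluded"))
  invisible(x)
}

#' Aggregate included fits into a whole-brain HRF
#'
#' Evaluates every included fitted HRF on a common grid, normalizes each to
#' unit maximum, averages pointwise, and recovers a single parameter set by
#' refitting the two-gamma form to the mean curve (the amplitude is fixed by
#' the normalization). Parameter vectors are not averaged directly because
#' the family is not closed under parameter averaging.
#'
#' @param fits list of `hrf_fit` objects (only `included` ones are used,
#'   unless none is included, which is an error).
#' @param grid evaluation time grid.
#' @param seed seed for the refit multi-start.
#' @return List with `curve` (mean normalized `hrf_curve`), `params`
#'   (refitted [hrf_params()]), `n` (number of HRFs aggregated), and
#'   `refit_nmse`.
#' @export
aggregate_whole_brain <- function(fits, grid = hrf_time_grid(), seed = 1) {
  fits <- Filter(function(f) isTRUE(f$included), fits)
  if (!length(fits)) stopf("no included fits to aggregate")
  curves <- vapply(fits, function(f)
    normalize_to_max(evaluate_hrf(f$params, grid))$value, numeric(length(grid)))
  mean_curve <- rowMeans(curves)
  mc <- hrf_curve(grid, mean_curve)

  ## refit the two-gamma shape to the mean curve
  bounds <- default_hrf_bounds()
  obj <- function(p) hrf_eval_raw(grid, p[1], p[2], p[3], p[3] + p[4], p[5]) - mean_curve
  best <- NULL
  withr::with_seed(seed, {
    for (s in 1:8) {
      start <- c(A = 1, b = 1, p1 = 5, dp = 5, V = 2) * exp(stats::runif(5, -0.4, 0.4))
      start <- pmin(pmax(start, bounds$lower), bounds$upper)
      fit <- tryCatch(minpack.lm::nls.lm(start, lower = bounds$lower,
                                         upper = bounds$upper, fn = obj,
                                         control = minpack.lm::nls.lm.control(maxiter = 300)),
                      error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance)) best <- fit
    }
  })
  if (is.null(best)) stopf("whole-brain refit failed")
  par <- stats::coef(best)
  params <- hrf_params(A = par[["A"]], b = par[["b"]], p1 = par[["p1"]],
                       p2 = par[["p1"]] + par[["dp"]], V = par[["V"]])
  list(curve = mc, params = params, n = length(fits),
       refit_nmse = compute_nmse(mean_curve,
                                 hrf_eval_raw(grid, par[1], par[2], par[3],
                                              par[3] + par[4], par[5])))
}

#' Export a table of structure fits
#'
#' @param fits named list of `hrf_fit` objects (names = structure labels).
#' @param path optional TSV output path.
#' @param group optional group tag column.
#' @return data.frame with one row per fit (structure, A, b, p1, p2, V,
#'   nmse, onset, converged, included).
#' @export
fit_table <- function(fits, path = NULL, group = NA_character_) {
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    p <- f$params
    data.frame(structure = nm, group = group,
               A = p$A %||% NA_real_, b = p$b %||% NA_real_,
               p1 = p$p1 %||% NA_real_, p2 = p$p2 %||% NA_real_,
               V = p$V %||% NA_real_, nmse = f$nmse, onset = f$onset,
               converged = f$converged, included = f$included)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(structure = character(0), group = character(0), A = numeric(0),
               b = numeric(0), p1 = numeric(0), p2 = numeric(0), V = numeric(0),
               nmse = numeric(0), onset = numeric(0), converged = logical(0),
               included = logical(0))
  if (!is.null(path)) write_tsv(df, path)
  df
}
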