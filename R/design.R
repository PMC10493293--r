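#' Block-design stimulation paradigm
#'
#' Describes a repeated stimulation/rest block design. The default matches a
#' 20-block paradigm with 10 s stimulation and 20 s rest at TR = 1 s, a 1 Hz
#' pulse train with 0.5 s pulses during stimulation, and a 10 s pre-onset
#' baseline window before the first analyzed block.
#'
#' @param n_blocks number of stimulation blocks.
#' @param stim_duration stimulation duration per block (s).
#' @param rest_duration rest duration per block (s).
#' @param TR repetition time between volumes (s).
#' @param pre_window baseline interval before the first analyzed onset (s).
#' @param pulse_frequency stimulus pulse rate within a block (Hz).
#' @param pulse_duration single pulse duration (s).
#' @return An object of class `block_paradigm`.
#' @export
block_paradigm <- function(n_blocks = 20, stim_duration = 10, rest_duration = 20,
                           TR = 1, pre_window = 10,
                           pulse_frequency = 1, pulse_duration = 0.5) {
  if (n_blocks < 1) stopf("n_blocks must be >= 1")
  if (stim_duration <= 0 || rest_duration <= 0) stopf("block durations must be positive")
  if (TR <= 0) stopf("TR must be positive")
  if (pre_window < 0) stopf("pre_window must be non-negative")
  if (pulse_frequency * pulse_duration > 1 + 1e-9)
    stopf("pulse_frequency * pulse_duration must not exceed 1 (duty cycle)")
  structure(list(n_blocks = as.integer(n_blocks), stim_duration = stim_duration,
                 rest_duration = rest_duration, TR = TR, pre_window = pre_window,
                 pulse_frequency = pulse_frequency, pulse_duration = pulse_duration),
            class = "block_paradigm")
}

#' @export
print.block_paradigm <- function(x, ...) {
  cat(sprintf("Block paradigm: %d blocks of %g s stimulation / %g s rest, TR %g s\n",
              x$n_blocks, x$stim_duration, x$rest_duration, x$TR))
  invisible(x)
}

cycle_length <- function(paradigm) paradigm$stim_duration + paradigm$rest_duration

#' Block onset times
#'
#' Onsets of each stimulation block on the acquisition clock (time 0 = first
#' stored volume). The first `n_discard` volumes are treated as pre-steady-state
#' and precede the analyzed series, so the first onset falls at
#' `n_discard * TR + pre_window`.
#'
#' @param paradigm a [block_paradigm()].
#' @param n_discard number of initial volumes discarded before analysis.
#' @return Numeric vector of onset times (s).
#' @export
block_onsets <- function(paradigm, n_discard = 0) {
  n_discard * paradigm$TR + paradigm$pre_window +
    (seq_len(paradigm$n_blocks) - 1) * cycle_length(paradigm)
}

#' Fine-grid stimulus function of a block paradigm
#'
#' Builds the stimulus envelope on a fine time grid: 1 during stimulation
#' blocks and 0 otherwise. With `pulse_level = TRUE` the 1 Hz pulse train
#' inside each block is resolved instead of the block envelope.
#'
#' @inheritParams block_onsets
#' @param dt fine grid spacing (s); must divide TR evenly.
#' @param total_time grid extent (s). Defaults to the paradigm span
#'   `pre_window + n_blocks * (stim + rest)` plus the discarded lead-in.
#' @param pulse_level resolve individual pulses instead of the block envelope.
#' @return List of class `stimulus` with `time`, `value` and `dt`.
#' @export
boxcar <- function(paradigm, dt = 0.05, total_time = NULL, n_discard = 0,
                   pulse_level = FALSE) {
  ratio <- paradigm$TR / dt
  if (!near(ratio, round(ratio))) stopf("dt (%g) must divide TR (%g) evenly", dt, paradigm$TR)
  total_time <- total_time %||%
    (n_discard * paradigm$TR + paradigm$pre_window +
       paradigm$n_blocks * cycle_length(paradigm))
  time <- seq(0, total_time, by = dt)
  value <- numeric(length(time))
  for (onset in block_onsets(paradigm, n_discard)) {
    if (pulse_level) {
      n_pulses <- floor(paradigm$stim_duration * paradigm$pulse_frequency)
      starts <- onset + (seq_len(n_pulses) - 1) / paradigm$pulse_frequency
      for (ps in starts) value[time >= ps & time < ps + paradigm$pulse_duration] <- 1
    } else {
      value[time >= onset & time < onset + paradigm$stim_duration] <- 1
    }
  }
  structure(list(time = time, value = value, dt = dt), class = "stimulus")
}

#' Convolve a stimulus function with an HRF and sample at volume times
#'
#' Discrete approximation of the continuous convolution on the common fine
#' grid (scaled by `dt`), truncated to the stimulus window and sampled at
#' volume acquisition times `0, TR, 2 TR, ...`.
#'
#' @param stimulus a [boxcar()] stimulus (or any list with `time`, `value`, `dt`).
#' @param hrf an `hrf_curve` on a grid with the same spacing `dt`.
#' @param TR sampling interval of the volumes (s).
#' @param n_volumes number of volumes to sample; defaults to all that fit in
#'   the stimulus window.
#' @return Numeric vector: the regressor at each volume.
#' @export
convolve_with_hrf <- function(stimulus, hrf, TR, n_volumes = NULL) {
  stopifnot(inherits(hrf, "hrf_curve"))
  hdt <- if (length(hrf$time) > 1) hrf$time[2] - hrf$time[1] else stimulus$dt
  if (!near(hdt, stimulus$dt)) stopf("stimulus dt (%g) and HRF dt (%g) differ", stimulus$dt, hdt)
  fine <- fft_convolve(stimulus$value, hrf$value, dt = stimulus$dt,
                       n_out = length(stimulus$value))
  t_end <- stimulus$time[length(stimulus$time)]
  n_max <- floor(t_end / TR) + 1L
  n_volumes <- n_volumes %||% n_max
  if (n_volumes > n_max) stopf("stimulus window too short for %d volumes", n_volumes)
  idx <- round((seq_len(n_volumes) - 1) * TR / stimulus$dt) + 1L
  fine[idx]
}

## shared scaffolding: nuisance columns and design assembly
assemble_design <- function(task, labels, n_analyzed, include_drift) {
  X <- cbind(task, intercept = 1)
  lab <- c(labels, "intercept")
  if (include_drift) {
    X <- cbind(X, drift = seq_len(n_analyzed) - (n_analyzed + 1) / 2)
    lab <- c(lab, "drift")
  }
  colnames(X) <- lab
  if (qr(X)$rank < ncol(X)) stopf("design matrix is rank deficient")
  attr(X, "task_cols") <- seq_along(labels)
  class(X) <- c("fmri_design", class(X))
  X
}

#' Canonical HRF design matrix (1st or 3rd order)
#'
#' Order 1 has a single task regressor, the HRF convolved with the paradigm.
#' Order 3 adds the temporal and dispersion derivative regressors. An
#' intercept is always included; a centered linear drift column is optional.
#' The regressor is built over the full acquisition (including the discarded
#' lead-in volumes, so the analyzed series is in convolution steady state) and
#' then truncated to the analyzed volumes.
#'
#' @inheritParams block_onsets
#' @param params HRF parameters for the canonical regressors.
#' @param order 1 or 3.
#' @param n_volumes number of acquired volumes.
#' @param dt fine grid spacing used for the convolution (s).
#' @param include_drift add a linear drift column.
#' @return Design matrix (rows = analyzed volumes) with attribute `task_cols`.
#' @export
build_canonical_design <- function(paradigm, params, order = 1,
                                   n_volumes = 620, n_discard = 20,
                                   dt = 0.05, include_drift = FALSE) {
  if (!order %in% c(1, 3)) stopf("order must be 1 or 3")
  TR <- paradigm$TR
  stim <- boxcar(paradigm, dt = dt, total_time = n_volumes * TR, n_discard = n_discard)
  grid <- seq(0, 30, by = dt)
  basis <- list(task = evaluate_hrf(params, grid))
  if (order == 3) {
    dv <- hrf_basis_derivatives(params, grid)
    basis$task_tderiv <- dv$temporal
    basis$task_ddisp <- dv$dispersion
  }
  cols <- vapply(basis, function(h)
    convolve_with_hrf(stim, h, TR, n_volumes)[(n_discard + 1):n_volumes],
    numeric(n_volumes - n_discard))
  assemble_design(cols, names(basis), n_volumes - n_discard, include_drift)
}

#' Finite impulse response (FIR) design matrix
#'
#' `order` contiguous post-onset bins of width `window / order`; FIR column k
#' is 1 for volumes whose acquisition time falls in bin k of any block. The
#' default order-9 set over a 30 s window tiles one full block cycle with
#' nine boxcar functions.
#'
#' @inheritParams build_canonical_design
#' @param order number of FIR bins.
#' @param window post-onset window covered by the bins (s).
#' @return Design matrix (rows = analyzed volumes) with attribute `task_cols`.
#' @export
build_fir_design <- function(paradigm, order = 9, window = 30,
                             n_volumes = 620, n_discard = 20,
                             include_drift = FALSE) {
  if (order < 1) stopf("order must be >= 1")
  if (window <= 0) stopf("window must be positive")
  w <- window / order
  if (w < paradigm$TR - 1e-9)
    stopf("FIR bin width %g s is below the TR (%g s)", w, paradigm$TR)
  TR <- paradigm$TR
  n_an <- n_volumes - n_discard
  t_acq <- (n_discard:(n_volumes - 1)) * TR
  X <- matrix(0, nrow = n_an, ncol = order)
  for (onset in block_onsets(paradigm, n_discard)) {
    rel <- t_acq - onset
    inwin <- rel >= 0 & rel < window
    bin <- floor(rel[inwin] / w) + 1L
    X[cbind(which(inwin), bin)] <- 1
  }
  assemble_design(X, paste0("fir", seq_len(order)), n_an, include_drift)
}

#' Read and write block events tables
#'
#' Tab-separated events files with columns `onset` (s), `duration` (s) and
#' `trial_type`, one row per stimulation block, on the acquisition clock.
#'
#' @param paradigm a [block_paradigm()].
#' @param path file path.
#' @param n_discard discarded lead-in volumes offsetting the first onset.
#' @param trial_type label written in the `trial_type` column.
#' @return `read_events` returns a data.frame; `write_events` returns `path`
#'   invisibly.
#' @export
write_events <- function(paradigm, path, n_discard = 0, trial_type = "stim") {
  df <- data.frame(onset = block_onsets(paradigm, n_discard),
                   duration = paradigm$stim_duration,
                   trial_type = trial_type)
  write_tsv(df, path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- read_tsv(path)
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(df))) stopf("events file must have columns %s",
                                       paste(need, collapse = ", "))
  df
}

#' Export a design matrix as TSV
#'
#' @param design a design matrix from [build_canonical_design()] or
#'   [build_fir_design()].
#' @param path file path.
#' @export
write_design <- function(design, path) {
  write_tsv(as.data.frame(unclass(design)), path)
  invisible(path)
}
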