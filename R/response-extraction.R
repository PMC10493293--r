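#' Extract voxel time courses by structure from activated voxels
#'
#' Returns, for each atlas structure, the time courses of the voxels that are
#' both inside the structure and inside the activation mask.
#'
#' @param data4d 4D array whose 4th extent is the number of analyzed volumes.
#' @param labels integer 3D atlas volume.
#' @param active_mask logical 3D activation mask.
#' @return Named list (one element per structure with any retained voxel) of
#'   time-by-voxel matrices; each matrix carries a `voxels` attribute with
#'   the linear voxel indices.
#' @export
extract_voxel_timecourses <- function(data4d, labels, active_mask) {
  dims <- dim(data4d)[1:3]
  if (!identical(dims, dim(labels)) || !identical(dims, dim(active_mask)))
    stopf("data, labels and mask must share spatial dimensions")
  nt <- dim(data4d)[4]
  flat <- matrix(data4d, ncol = nt)
  out <- list()
  for (s in sort(unique(labels[labels > 0L]))) {
    vox <- which(labels == s & active_mask)
    if (!length(vox)) next
    m <- t(flat[vox, , drop = FALSE])
    attr(m, "voxels") <- vox
    out[[as.character(s)]] <- m
  }
  out
}

#' Temporal moving-average smoothing
#'
#' Centered moving average with the window rounded to an odd number of
#' samples; shrinking windows are used at the series edges. The default 5 s
#' window at TR = 1 s averages 5 samples.
#'
#' @param series numeric vector (or time-by-voxel matrix, smoothed per column).
#' @param window smoothing window (s).
#' @param TR sampling interval (s).
#' @return Smoothed series of the same shape.
#' @export
smooth_temporal <- function(series, window = 5, TR = 1) {
  if (window < TR) stopf("window must be at least one TR")
  if (is.matrix(series)) return(apply(series, 2, smooth_temporal, window = window, TR = TR))
  k <- round(window / TR)
  if (k %% 2 == 0) k <- k + 1L
  if (k <= 1L) return(series)
  h <- (k - 1L) %/% 2L
  n <- length(series)
  cs <- cumsum(c(0, series))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Epoch-average a time course over paradigm cycles
#'
#' Folds the analyzed series into one stimulation cycle (30 s for the default
#' paradigm), with each epoch starting `pre_window` seconds before its block
#' onset, averages across cycles, and converts to % signal change relative to
#' the mean of the pre-onset baseline window. The baseline mean of the output
#' is 0 by construction.
#'
#' @param series numeric vector: the analyzed time course (first analyzed
#'   volume at time 0, onset of the first block at `pre_window`).
#' @param paradigm a [block_paradigm()].
#' @param n_voxels number of voxels the series represents (metadata).
#' @param structure structure label (metadata).
#' @return An object of class `epoch_curve`: list with `time` (s within the
#'   cycle; stimulus onset at `pre_window`), `value` (% signal change),
#'   `n_cycles`, `n_voxels`, `structure`.
#' @export
epoch_average <- function(series, paradigm, n_voxels = 1L, structure = NA) {
  TR <- paradigm$TR
  n_cycle <- round(cycle_length(paradigm) / TR)
  n_full <- floor(length(series) / n_cycle)
  if (n_full < 2) stopf("need at least 2 complete cycles (%d samples each)", n_cycle)
  m <- matrix(series[seq_len(n_full * n_cycle)], nrow = n_cycle)
  ep <- rowMeans(m)
  n_base <- round(paradigm$pre_window / TR)
  if (n_base < 1) stopf("pre_window shorter than one TR: no baseline window")
  base <- mean(ep[seq_len(n_base)])
  if (base == 0) stopf("degenerate series: zero baseline level")
  value <- 100 * (ep - base) / base
  structure(list(time = (seq_len(n_cycle) - 1) * TR, value = value,
                 n_cycles = n_full, n_voxels = n_voxels, structure = structure,
                 pre_window = paradigm$pre_window, TR = TR),
            class = "epoch_curve")
}

#' @export
print.epoch_curve <- function(x, ...) {
  cat(sprintf("Epoch curve (structure %s): %d samples over %g s, peak %.3g%%, %d voxel(s)\n",
              as.character(x$structure), length(x$time),
              x$time[length(x$time)] + x$TR, max(x$value), x$n_voxels))
  invisible(x)
}

#' Classify the polarity of an epoch-averaged BOLD response
#'
#' A curve is positive when (1) its peak amplitude reaches `amp_min` percent
#' signal change and (2) the signal decays by at least `decay_min` of the
#' peak after the maximum (post-peak minimum at or below
#' `(1 - decay_min) * peak`). It is negative when the inverted curve
#' satisfies both criteria, and unclassified otherwise.
#'
#' @param curve an [epoch_average()] curve (baseline-normalized).
#' @param amp_min minimum peak amplitude (% signal change).
#' @param decay_min minimum post-peak decay (fraction of the peak).
#' @return `"positive"`, `"negative"` or `"unclassified"`.
#' @export
classify_polarity <- function(curve, amp_min = 0.6, decay_min = 0.4) {
  v <- curve$value
  meets <- function(v) {
    ipk <- which.max(v)
    pk <- v[ipk]
    if (pk < amp_min) return(FALSE)
    if (ipk == length(v)) return(FALSE)
    min(v[(ipk + 1):length(v)]) <= (1 - decay_min) * pk
  }
  if (meets(v)) "positive" else if (meets(-v)) "negative" else "unclassified"
}

#' Structure mean curve over positively responding voxels
#'
#' Averages voxel epoch curves within a structure, provided the structure has
#' more than `min_voxels` contributing voxels (default: more than 4, i.e. at
#' least 5); otherwise the structure is skipped.
#'
#' @param curves list of `epoch_curve` objects on a common grid.
#' @param min_voxels structures are kept only when the voxel count strictly
#'   exceeds this.
#' @param structure structure label (metadata).
#' @return An `epoch_curve` (the voxelwise mean) or `NULL` when the structure
#'   has too few voxels.
#' @export
structure_mean_curve <- function(curves, min_voxels = 4, structure = NA) {
  stopifnot(is.list(curves))
  n <- length(curves)
  if (n <= min_voxels) return(NULL)
  tmpl <- curves[[1]]
  for (cv in curves)
    if (!isTRUE(all.equal(cv$time, tmpl$time))) stopf("curves must share the time grid")
  vals <- rowMeans(vapply(curves, `[[`, numeric(length(tmpl$value)), "value"))
  out <- tmpl
  out$value <- vals
  out$n_voxels <- n
  out$structure <- structure
  out
}
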