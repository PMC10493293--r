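#' Specification of a synthetic labeled BOLD dataset
#'
#' Defines the acquisition geometry and the response statistics the generator
#' emulates: TR 1 s, 620 volumes with the first 20 discarded, about 8.36% of
#' in-brain voxels carrying positive responses with a mean amplitude of
#' 0.838% signal change, and an atlas of 30 labeled structures.
#'
#' @param dims spatial grid (x, y, z voxels).
#' @param n_structures number of atlas structures.
#' @param TR repetition time (s).
#' @param n_volumes acquired volumes.
#' @param n_discard initial volumes discarded before analysis.
#' @param responder_fraction proportion of in-brain voxels given positive
#'   responses.
#' @param response_amplitude_mean,response_amplitude_sd per-voxel response
#'   amplitude distribution (% signal change).
#' @param hrf_params generating HRF parameters.
#' @param noise_sd white temporal noise SD (% signal change).
#' @param drift_slope linear drift (% per volume).
#' @param negative_fraction proportion of in-brain voxels with inverted
#'   responses.
#' @param patch_size mean size (voxels) of the contiguous responder patches;
#'   patches never fall below 6 voxels so true activation is not removable by
#'   the cluster-extent rule alone.
#' @param seed RNG seed; generation is deterministic given the seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(dims = c(24, 24, 12), n_structures = 30, TR = 1,
                           n_volumes = 620, n_discard = 20,
                           responder_fraction = 0.0836,
                           response_amplitude_mean = 0.838,
                           response_amplitude_sd = 0.1,
                           hrf_params = hrf_preset("mouse"),
                           noise_sd = 0.2, drift_slope = 0,
                           negative_fraction = 0, patch_size = 15, seed = 1) {
  if (any(dims < 1)) stopf("dims must be positive")
  if (n_discard >= n_volumes) stopf("n_discard must be below n_volumes")
  for (f in c(responder_fraction, negative_fraction))
    if (f < 0 || f > 1) stopf("fractions must lie in [0, 1]")
  if (responder_fraction + negative_fraction > 1)
    stopf("responder_fraction + negative_fraction must not exceed 1")
  structure(list(dims = as.integer(dims), n_structures = as.integer(n_structures),
                 TR = TR, n_volumes = as.integer(n_volumes),
                 n_discard = as.integer(n_discard),
                 responder_fraction = responder_fraction,
                 response_amplitude_mean = response_amplitude_mean,
                 response_amplitude_sd = response_amplitude_sd,
                 hrf_params = hrf_params, noise_sd = noise_sd,
                 drift_slope = drift_slope, negative_fraction = negative_fraction,
                 patch_size = patch_size, seed = as.integer(seed)),
            class = "synthetic_spec")
}

## ellipsoidal in-brain mask centered in the grid
brain_mask <- function(dims) {
  cx <- (dims + 1) / 2
  semi <- dims / 2 - 0.5
  ix <- slice.index(array(0, dims), 1)
  iy <- slice.index(array(0, dims), 2)
  iz <- slice.index(array(0, dims), 3)
  ((ix - cx[1]) / semi[1])^2 + ((iy - cx[2]) / semi[2])^2 +
    ((iz - cx[3]) / semi[3])^2 <= 1
}

## multi-source BFS region growth from seed voxels over a 6-neighbourhood,
## restricted to `mask`; returns integer labels over the full grid
grow_regions <- function(dims, mask, seeds) {
  lab <- array(0L, dims)
  lab[seeds] <- seq_along(seeds)
  frontier <- seeds
  while (length(frontier)) {
    nb <- array_neighbors6(frontier, dims)
    nxt <- integer(0)
    for (d in seq_along(nb)) {
      to <- nb[[d]]
      ok <- !is.na(to)
      ok[ok] <- mask[to[ok]] & lab[to[ok]] == 0L
      if (any(ok)) {
        ## first writer wins within a round; duplicated targets resolved by order
        to_ok <- to[ok]; from_ok <- frontier[ok]
        keep <- !duplicated(to_ok)
        to_ok <- to_ok[keep]; from_ok <- from_ok[keep]
        still <- lab[to_ok] == 0L
        lab[to_ok[still]] <- lab[from_ok[still]]
        nxt <- c(nxt, to_ok[still])
      }
    }
    frontier <- sample(nxt)
  }
  lab
}

#' Generate a synthetic integer-labeled atlas volume
#'
#' Seeded multi-source region growth inside an ellipsoidal in-brain mask
#' produces contiguous, compact structures. Seeds are resampled until every
#' structure has at least 10 voxels, so generation is deterministic given the
#' seed.
#'
#' @param dims spatial grid (x, y, z voxels).
#' @param n_structures number of structures.
#' @param seed RNG seed.
#' @return Integer 3D array: 0 = background, 1..n_structures inside the brain.
#' @export
generate_atlas <- function(dims = c(24, 24, 12), n_structures = 30, seed = 1) {
  dims <- as.integer(dims)
  mask <- brain_mask(dims)
  inbrain <- which(mask)
  if (n_structures > length(inbrain) / 10)
    stopf("grid too small: %d structures need at least %d in-brain voxels",
          n_structures, 10 * n_structures)
  withr::with_seed(seed, {
    for (attempt in 1:100) {
      seeds <- sample(inbrain, n_structures)
      lab <- grow_regions(dims, mask, seeds)
      sizes <- tabulate(lab[lab > 0L], nbins = n_structures)
      if (min(sizes) >= 10) return(lab)
    }
  })
  stopf("could not place %d structures of >= 10 voxels in this grid", n_structures)
}

## grow contiguous responder patches totalling n_total voxels inside `eligible`
## (logical array); returns voxel indices. Patches are >= min_patch voxels
## except when space runs out, in which case leftovers extend earlier patches.
sample_patches <- function(dims, eligible, n_total, patch_mean, min_patch = 6L) {
  chosen <- integer(0)
  free <- eligible
  remaining <- n_total
  while (remaining > 0L) {
    pool <- which(free)
    if (!length(pool)) break
    target <- max(min_patch, round(stats::rnorm(1, patch_mean, patch_mean / 3)))
    target <- min(target, remaining)
    if (remaining - target < min_patch) target <- remaining
    patch <- sample(pool, 1)
    free[patch] <- FALSE
    frontier <- patch
    while (length(patch) < target && length(frontier)) {
      nb <- unlist(array_neighbors6(frontier, dims))
      nb <- nb[!is.na(nb)]
      nb <- unique(nb[free[nb]])
      if (!length(nb)) break
      take <- utils::head(sample(nb), target - length(patch))
      free[take] <- FALSE
      patch <- c(patch, take)
      frontier <- take
    }
    if (length(patch) < min_patch && length(chosen)) {
      ## pocket too small to stand alone: graft onto the boundary of an
      ## existing patch instead
      free[patch] <- TRUE
      grafted <- 0L
      nb <- unlist(array_neighbors6(chosen, dims))
      nb <- unique(nb[!is.na(nb)])
      nb <- nb[free[nb]]
      take <- utils::head(sample(nb), length(patch))
      free[take] <- FALSE
      chosen <- c(chosen, take)
      remaining <- remaining - length(take)
      if (!length(take)) break
      next
    }
    chosen <- c(chosen, patch)
    remaining <- remaining - length(patch)
  }
  chosen
}

#' Generate a labeled 4D BOLD dataset with known ground truth
#'
#' Responder voxels carry `baseline + amplitude * (peak-normalized HRF
#' regressor) + drift + noise`, where the regressor is the generating HRF
#' convolved with the block paradigm over the full acquisition (so the
#' analyzed series is in steady state). The baseline level is 100, making raw
#' values directly interpretable as 100 + % signal change. Responder voxels
#' form contiguous patches; their count is drawn Binomial(n in-brain,
#' responder_fraction). Background (out-of-brain) voxels are zero.
#'
#' @param spec a [synthetic_spec()].
#' @param paradigm a [block_paradigm()]; its TR must match the spec.
#' @return An object of class `labeled_dataset`: list with the 4D `data`
#'   array, integer `labels` volume, per-voxel `truth` data.frame (columns
#'   `voxel`, `x`, `y`, `z`, `structure`, `class`, `amplitude`), the
#'   peak-normalized `regressor`, and the generating `spec` and `paradigm`.
#' @export
generate_dataset <- function(spec, paradigm = block_paradigm(TR = spec$TR)) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(paradigm, "block_paradigm"))
  if (!near(paradigm$TR, spec$TR)) stopf("paradigm TR and spec TR differ")
  dims <- spec$dims
  labels <- generate_atlas(dims, spec$n_structures, seed = spec$seed)
  inbrain <- which(labels > 0L)
  n_in <- length(inbrain)

  dt <- 0.05
  stim <- boxcar(paradigm, dt = dt, total_time = spec$n_volumes * spec$TR,
                 n_discard = spec$n_discard)
  hrf <- evaluate_hrf(spec$hrf_params, hrf_time_grid(30, dt))
  reg <- convolve_with_hrf(stim, hrf, spec$TR, spec$n_volumes)
  reg <- reg / max(reg)  # peak % signal change = amplitude

  withr::with_seed(spec$seed + 1L, {
    n_pos <- stats::rbinom(1, n_in, spec$responder_fraction)
    eligible <- labels > 0L
    pos_idx <- sample_patches(dims, eligible, n_pos, spec$patch_size)
    neg_idx <- integer(0)
    if (spec$negative_fraction > 0) {
      n_neg <- stats::rbinom(1, n_in, spec$negative_fraction)
      eligible[pos_idx] <- FALSE
      neg_idx <- sample_patches(dims, eligible, n_neg, spec$patch_size)
    }
    cls <- rep("none", n_in)
    names(cls) <- inbrain
    cls[as.character(pos_idx)] <- "positive"
    cls[as.character(neg_idx)] <- "negative"
    amp <- rep(0, n_in)
    responders <- c(pos_idx, neg_idx)
    amp_draw <- stats::rnorm(length(responders), spec$response_amplitude_mean,
                             spec$response_amplitude_sd)
    amp_draw <- pmax(amp_draw, 0.05)  # amplitudes are positive by construction
    amp[match(responders, inbrain)] <- amp_draw

    nt <- spec$n_volumes
    drift <- spec$drift_slope * (seq_len(nt) - 1)
    Y <- matrix(100 + rep(drift, n_in), nrow = nt, ncol = n_in)
    if (spec$noise_sd > 0)
      Y <- Y + matrix(stats::rnorm(nt * n_in, 0, spec$noise_sd), nrow = nt)
    ip <- match(pos_idx, inbrain)
    if (length(ip)) Y[, ip] <- Y[, ip] + outer(reg, amp[ip])
    im <- match(neg_idx, inbrain)
    if (length(im)) Y[, im] <- Y[, im] - outer(reg, amp[im])
  })

  data4d <- array(0, c(dims, spec$n_volumes))
  flat <- matrix(data4d, nrow = prod(dims))
  flat[inbrain, ] <- t(Y)
  data4d <- array(flat, c(dims, spec$n_volumes))

  coords <- arrayInd(inbrain, dims)
  truth <- data.frame(voxel = inbrain, x = coords[, 1], y = coords[, 2],
                      z = coords[, 3], structure = labels[inbrain],
                      class = unname(cls), amplitude = amp)
  structure(list(data = data4d, labels = labels, truth = truth,
                 regressor = reg, spec = spec, paradigm = paradigm),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("Labeled BOLD dataset: %s voxels x %d volumes, %d structures\n",
              paste(x$spec$dims, collapse = "x"), x$spec$n_volumes,
              x$spec$n_structures))
  cat(sprintf("  %d positive / %d negative responders among %d in-brain voxels\n",
              sum(x$truth$class == "positive"), sum(x$truth$class == "negative"),
              nrow(x$truth)))
  invisible(x)
}

#' Write and read a labeled dataset on disk
#'
#' The 4D signal and the integer atlas go to NIfTI-1 (`bold.nii.gz`,
#' `labels.nii.gz`), the block events to TSV (`events.tsv`), and the
#' ground-truth voxel table plus generation parameters to `truth.tsv` /
#' `truth.json`.
#'
#' @param dataset a `labeled_dataset`.
#' @param dir output directory (created if missing).
#' @return `write_dataset` returns `dir` invisibly; `read_dataset` returns a
#'   `labeled_dataset` (without regenerating the ground-truth record when the
#'   truth files are absent).
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  RNifti::writeNifti(dataset$data, file.path(dir, "bold.nii.gz"))
  RNifti::writeNifti(dataset$labels, file.path(dir, "labels.nii.gz"),
                     datatype = "int16")
  write_events(dataset$paradigm, file.path(dir, "events.tsv"),
               n_discard = dataset$spec$n_discard)
  write_tsv(dataset$truth, file.path(dir, "truth.tsv"))
  meta <- dataset$spec
  meta$hrf_params <- unclass(meta$hrf_params)
  jsonlite::write_json(list(spec = unclass(meta),
                            paradigm = unclass(dataset$paradigm)),
                       file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  data4d <- as.array(RNifti::readNifti(file.path(dir, "bold.nii.gz")))
  labels <- as.array(RNifti::readNifti(file.path(dir, "labels.nii.gz")))
  storage.mode(labels) <- "integer"
  meta <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  hp <- meta$spec$hrf_params
  spec <- synthetic_spec(dims = meta$spec$dims, n_structures = meta$spec$n_structures,
                         TR = meta$spec$TR, n_volumes = meta$spec$n_volumes,
                         n_discard = meta$spec$n_discard,
                         responder_fraction = meta$spec$responder_fraction,
                         response_amplitude_mean = meta$spec$response_amplitude_mean,
                         response_amplitude_sd = meta$spec$response_amplitude_sd,
                         hrf_params = hrf_params(hp$A, hp$b, hp$p1, hp$p2, hp$V,
                                                 hp$species %||% NA_character_),
                         noise_sd = meta$spec$noise_sd,
                         drift_slope = meta$spec$drift_slope,
                         negative_fraction = meta$spec$negative_fraction,
                         patch_size = meta$spec$patch_size, seed = meta$spec$seed)
  pd <- meta$paradigm
  paradigm <- block_paradigm(pd$n_blocks, pd$stim_duration, pd$rest_duration,
                             pd$TR, pd$pre_window, pd$pulse_frequency,
                             pd$pulse_duration)
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path)) read_tsv(truth_path) else NULL
  structure(list(data = data4d, labels = labels, truth = truth,
                 regressor = NULL, spec = spec, paradigm = paradigm),
            class = "labeled_dataset")
}

#' Generate per-group datasets
#'
#' Thin wrapper assigning group-specific responder fractions and amplitudes
#' (e.g. male/female crossed with stimulus modality) so group-level analyses
#' of activated voxel counts can be exercised on synthetic data.
#'
#' @param base_spec a [synthetic_spec()] providing shared settings.
#' @param groups data.frame with columns `group`, and optionally
#'   `responder_fraction`, `response_amplitude_mean`, `seed`.
#' @param paradigm a [block_paradigm()].
#' @return Named list of `labeled_dataset` objects.
#' @export
generate_group_datasets <- function(base_spec, groups,
                                    paradigm = block_paradigm(TR = base_spec$TR)) {
  out <- list()
  for (i in seq_len(nrow(groups))) {
    sp <- base_spec
    if (!is.null(groups$responder_fraction))
      sp$responder_fraction <- groups$responder_fraction[i]
    if (!is.null(groups$response_amplitude_mean))
      sp$response_amplitude_mean <- groups$response_amplitude_mean[i]
    sp$seed <- if (!is.null(groups$seed)) as.integer(groups$seed[i])
               else base_spec$seed + i
    out[[groups$group[i]]] <- generate_dataset(sp, paradigm)
  }
  out
}
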