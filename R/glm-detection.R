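## Gaussian kernel matrix for one axis, FWHM in voxel units, rows renormalized
## (truncation at 4 sigma) so constants are preserved.
gauss_kernel_matrix <- function(n, fwhm) {
  if (fwhm <= 0) return(diag(n))
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  d <- outer(seq_len(n), seq_len(n), "-")
  K <- exp(-d^2 / (2 * sigma^2))
  K[abs(d) > 4 * sigma] <- 0
  K / rowSums(K)
}

#' Spatial Gaussian smoothing of a 4D series
#'
#' Separable per-volume Gaussian smoothing with an axis-wise FWHM given in
#' voxel units. A FWHM of 0 on an axis leaves that axis untouched; edge
#' kernels are renormalized so constant volumes are preserved.
#'
#' @param data4d 4D array (x, y, z, time) or a 3D volume.
#' @param fwhm FWHM per axis in voxels (length 1 or 3).
#' @return Smoothed array of the same shape.
#' @export
smooth_spatial <- function(data4d, fwhm) {
  if (any(fwhm < 0)) stopf("fwhm must be non-negative")
  fwhm <- rep(fwhm, length.out = 3)
  dims <- dim(data4d)
  is3d <- length(dims) == 3L
  if (is3d) { data4d <- array(data4d, c(dims, 1L)); dims <- dim(data4d) }
  Ks <- lapply(1:3, function(a) gauss_kernel_matrix(dims[a], fwhm[a]))
  out <- data4d
  for (v in seq_len(dims[4])) {
    vol <- out[, , , v]
    ## contract each spatial axis with its kernel
    m <- Ks[[1]] %*% matrix(vol, dims[1])
    vol <- array(m, dims[1:3])
    vol <- aperm(vol, c(2, 1, 3))
    m <- Ks[[2]] %*% matrix(vol, dims[2])
    vol <- aperm(array(m, dims[c(2, 1, 3)]), c(2, 1, 3))
    vol <- aperm(vol, c(3, 1, 2))
    m <- Ks[[3]] %*% matrix(vol, dims[3])
    vol <- aperm(array(m, dims[c(3, 1, 2)]), c(2, 3, 1))
    out[, , , v] <- vol
  }
  if (is3d) out[, , , 1] else out
}

#' Voxelwise ordinary least squares GLM
#'
#' Fits the design to every voxel time course by OLS. Degrees of freedom are
#' `rows - columns` of the design.
#'
#' @param data4d 4D array (x, y, z, time) whose 4th extent equals the number
#'   of analyzed volumes, or a time-by-voxel matrix.
#' @param design design matrix from [build_canonical_design()] or
#'   [build_fir_design()].
#' @param mask optional logical 3D array restricting the fit (default: voxels
#'   with nonzero temporal variance or any nonzero value).
#' @return An object of class `glm_fit`: coefficients (`beta`, columns =
#'   voxels), residual variance `sigma2`, `df`, the design, and the spatial
#'   layout (`dims`, `voxels`).
#' @export
fit_glm <- function(data4d, design, mask = NULL) {
  if (qr(design)$rank < ncol(design)) stopf("design matrix is rank deficient")
  if (is.matrix(data4d)) {
    Y <- data4d
    dims <- NULL
    voxels <- seq_len(ncol(Y))
  } else {
    dims <- dim(data4d)[1:3]
    nt <- dim(data4d)[4]
    if (is.null(mask)) {
      flat <- matrix(data4d, ncol = nt)
      mask <- array(matrixStats_rowAny(flat != 0), dims)
    }
    voxels <- which(mask)
    Y <- t(matrix(data4d, ncol = nt)[voxels, , drop = FALSE])
  }
  if (nrow(Y) != nrow(design))
    stopf("data has %d volumes but design has %d rows", nrow(Y), nrow(design))
  X <- unclass(design)
  qrx <- qr(X)
  beta <- qr.coef(qrx, Y)
  res <- Y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df
  structure(list(beta = beta, sigma2 = sigma2, df = df, design = design,
                 dims = dims, voxels = voxels,
                 xtx_inv = chol2inv(qr.R(qrx))),
            class = "glm_fit")
}

## voxels with any nonzero sample (background is exactly zero)
matrixStats_rowAny <- function(m) rowSums(m) > 0

#' Task significance statistic per voxel
#'
#' For the 1st-order canonical basis a one-sided t statistic on the single
#' HRF regressor (positive BOLD responses); for the 3rd-order canonical and
#' FIR bases an F statistic over all task columns. Voxels with zero residual
#' variance get statistic 0 / p 1 when the task effect is also zero, and
#' p 0 when it is not (noise-free data fitted exactly).
#'
#' @param fit a [fit_glm()] result.
#' @param kind `"t"` (single task regressor, one-sided) or `"F"`; default
#'   chosen from the number of task columns.
#' @return An object of class `stat_map`: 3D arrays `stat` and `p` (when the
#'   fit carries spatial layout) plus `kind`, `df`.
#' @export
task_statistic <- function(fit, kind = NULL) {
  stopifnot(inherits(fit, "glm_fit"))
  task <- attr(fit$design, "task_cols")
  kind <- kind %||% if (length(task) == 1L) "t" else "F"
  eps <- 1e-12
  if (kind == "t") {
    if (length(task) != 1L) stopf("t statistic requires a single task column")
    b <- fit$beta[task, ]
    se2 <- fit$sigma2 * fit$xtx_inv[task, task]
    exact <- se2 < eps  # noise-free voxels fitted exactly
    stat <- numeric(length(b))
    stat[!exact] <- b[!exact] / sqrt(se2[!exact])
    big <- exact & abs(b) >= sqrt(eps)
    stat[big] <- Inf * sign(b[big])
    p <- stats::pt(stat, df = fit$df, lower.tail = FALSE)
    p[exact & !big] <- 1  # exact fit with zero task effect: definitely inactive
    dfs <- fit$df
  } else {
    q <- length(task)
    M <- solve(fit$xtx_inv[task, task, drop = FALSE])
    B <- fit$beta[task, , drop = FALSE]
    quad <- colSums((M %*% B) * B)  # beta' M beta per voxel
    stat <- ifelse(fit$sigma2 < eps,
                   ifelse(quad < eps, 0, Inf),
                   (quad / q) / fit$sigma2)
    p <- stats::pf(stat, q, fit$df, lower.tail = FALSE)
    dfs <- c(q, fit$df)
  }
  if (!is.null(fit$dims)) {
    stat_a <- array(0, fit$dims); p_a <- array(1, fit$dims)
    stat_a[fit$voxels] <- stat; p_a[fit$voxels] <- p
  } else {
    stat_a <- stat; p_a <- p
  }
  structure(list(stat = stat_a, p = p_a, kind = kind, df = dfs,
                 voxels = fit$voxels), class = "stat_map")
}

#' Threshold a statistic map with a cluster-extent rule
#'
#' Voxels with uncorrected p below `alpha` are retained, then connected
#' components (6-neighbourhood) of more than `min_cluster` voxels survive;
#' components of `min_cluster` voxels or fewer are removed.
#'
#' @param stat_map a [task_statistic()] result (or any list with a 3D `p`).
#' @param alpha uncorrected voxel threshold (strict `<`).
#' @param min_cluster minimum surviving cluster size is `min_cluster + 1`.
#' @return Logical 3D array (binary activation mask).
#' @export
threshold_map <- function(stat_map, alpha = 0.05, min_cluster = 5) {
  if (alpha <= 0 || alpha >= 1) stopf("alpha must lie in (0, 1)")
  supra <- stat_map$p < alpha
  if (!any(supra)) return(supra)
  lab <- label_components6(supra)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes > min_cluster)
  array(lab %in% keep, dim(supra))
}

#' Activation probability map
#'
#' Voxelwise mean of a group of binary activation masks.
#'
#' @param masks list of logical 3D arrays with common dimensions.
#' @return Numeric 3D array with values in `[0, 1]`.
#' @export
activation_probability <- function(masks) {
  if (!length(masks)) stopf("empty mask list")
  dims <- dim(masks[[1]])
  for (m in masks) if (!identical(dim(m), dims)) stopf("masks must share dimensions")
  Reduce(`+`, lapply(masks, function(m) m * 1)) / length(masks)
}

#' Dice similarity of two binary masks
#'
#' `2|A intersect B| / (|A| + |B|)`; two empty masks are defined as perfectly
#' similar (1).
#'
#' @param a,b logical arrays of identical dimensions.
#' @return Similarity in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stopf("masks must share dimensions")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}

#' Count activated voxels per atlas structure
#'
#' @param mask logical 3D activation mask.
#' @param labels integer 3D atlas (0 = background).
#' @return data.frame with columns `structure`, `n_voxels` (activated) and
#'   `size` (structure size).
#' @export
count_activated_voxels <- function(mask, labels) {
  if (!identical(dim(mask), dim(labels))) stopf("mask and labels must share dimensions")
  n <- max(labels)
  data.frame(structure = seq_len(n),
             n_voxels = tabulate(labels[mask & labels > 0L], nbins = n),
             size = tabulate(labels[labels > 0L], nbins = n))
}
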