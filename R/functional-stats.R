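#' Sample of curves on a common grid
#'
#' @param curves matrix with one curve per row (columns = time points), or a
#'   list of `hrf_curve`/`epoch_curve` objects sharing a grid.
#' @param group group label.
#' @return Object of class `curve_sample` (matrix with `group` attribute).
#' @export
curve_sample <- function(curves, group = NA_character_) {
  if (is.list(curves) && !is.matrix(curves)) {
    vals <- t(vapply(curves, `[[`, numeric(length(curves[[1]]$value)), "value"))
    curves <- vals
  }
  curves <- as.matrix(curves)
  if (nrow(curves) < 1) stopf("curve sample is empty")
  structure(curves, group = group, class = c("curve_sample", "matrix", "array"))
}

sample_matrix <- function(x) {
  if (inherits(x, "curve_sample") || is.matrix(x)) unclass(as.matrix(x)) else curve_sample(x)
}

## pointwise two-sample t on curve matrices (rows = curves)
pointwise_t_raw <- function(xm, ym) {
  nx <- nrow(xm); ny <- nrow(ym)
  mx <- colMeans(xm); my <- colMeans(ym)
  vx <- colSums(xm^2) - nx * mx^2
  vy <- colSums(ym^2) - ny * my^2
  vx <- pmax(vx / (nx - 1), 0)
  vy <- pmax(vy / (ny - 1), 0)
  num <- abs(mx - my)
  den2 <- vx / nx + vy / ny
  scale <- mean(c(xm^2, ym^2))
  floor_val <- 1e-12 * max(scale, .Machine$double.eps)
  t <- ifelse(den2 < floor_val & num < sqrt(floor_val), 0,
              num / sqrt(pmax(den2, floor_val)))
  t
}

#' Pointwise two-sample t curve
#'
#' Welch-style absolute t statistic per time point:
#' `|mean_x - mean_y| / sqrt(var_x / n_x + var_y / n_y)`. Time points where
#' both the mean difference and the pooled variance vanish give t = 0;
#' otherwise a variance floor (1e-12 of the squared sample scale) guards
#' against division by zero.
#'
#' @param x,y [curve_sample()] objects (or matrices, one curve per row) on a
#'   common grid, each with at least 2 curves.
#' @return Numeric vector: t at each time point.
#' @export
pointwise_t <- function(x, y) {
  xm <- sample_matrix(x); ym <- sample_matrix(y)
  if (ncol(xm) != ncol(ym)) stopf("samples must share the time grid")
  if (nrow(xm) < 2 || nrow(ym) < 2) stopf("each sample needs at least 2 curves")
  pointwise_t_raw(xm, ym)
}

#' Functional max-t permutation test for two samples of curves
#'
#' The observed statistic is the maximum over time of the pointwise absolute
#' t curve. Group labels are permuted; the p-value is the fraction `N / B` of
#' permutations whose max-t strictly exceeds the observed one. When the
#' number of distinct group splits is at most `exhaustive_max` (and
#' `exhaustive` is not `FALSE`), all splits are enumerated instead of
#' sampling, and the p-value is exact over the splits.
#'
#' @inheritParams pointwise_t
#' @param n_permutations number of label permutations.
#' @param seed RNG seed.
#' @param exhaustive force (`TRUE`) or forbid (`FALSE`) exhaustive
#'   enumeration; default `NULL` enumerates automatically when feasible.
#' @param exhaustive_max largest number of splits enumerated automatically.
#' @param plus_one use the (N+1)/(B+1) small-sample correction instead of the
#'   plain ratio N/B.
#' @return Object of class `ftest_result`: `t_curve`, `t_max`, `p`, `n_x`,
#'   `n_y`, `n_permutations`, `method`, `seed`.
#' @export
max_t_permutation_test <- function(x, y, n_permutations = 10000, seed = 1,
                                   exhaustive = NULL, exhaustive_max = 10000,
                                   plus_one = FALSE) {
  if (n_permutations < 1) stopf("n_permutations must be at least 1")
  xm <- sample_matrix(x); ym <- sample_matrix(y)
  if (ncol(xm) != ncol(ym)) stopf("samples must share the time grid")
  nx <- nrow(xm); ny <- nrow(ym)
  if (nx + ny < 3) stopf("need at least 3 curves in total")
  comb <- rbind(xm, ym)
  t_curve <- pointwise_t_raw(xm, ym)
  t_obs <- max(t_curve)

  n_splits <- choose(nx + ny, nx)
  do_exh <- if (is.null(exhaustive)) n_splits <= exhaustive_max else isTRUE(exhaustive)
  if (do_exh) {
    splits <- utils::combn(nx + ny, nx)
    tmax <- apply(splits, 2, function(ix)
      max(pointwise_t_raw(comb[ix, , drop = FALSE], comb[-ix, , drop = FALSE])))
    B <- ncol(splits)
    N <- sum(tmax > t_obs)
    method <- "exhaustive"
  } else {
    B <- n_permutations
    N <- 0L
    withr::with_seed(seed, {
      for (i in seq_len(B)) {
        ix <- sample.int(nx + ny, nx)
        tm <- max(pointwise_t_raw(comb[ix, , drop = FALSE], comb[-ix, , drop = FALSE]))
        if (tm > t_obs) N <- N + 1L
      }
    })
    method <- "monte-carlo"
  }
  p <- if (plus_one) (N + 1) / (B + 1) else N / B
  if (t_obs == 0) p <- 1  # no observed difference anywhere: nothing to reject
  structure(list(t_curve = t_curve, t_max = t_obs, p = p, n_x = nx, n_y = ny,
                 n_permutations = B, method = method, seed = seed),
            class = "ftest_result")
}

#' @export
print.ftest_result <- function(x, ...) {
  cat(sprintf("Functional max-t test: t_max = %.4g, p = %.4g (%s, %d permutations; n = %d vs %d)\n",
              x$t_max, x$p, x$method, x$n_permutations, x$n_x, x$n_y))
  invisible(x)
}

#' Bonferroni-adjusted significance threshold
#'
#' `alpha / m`, with a display value rounded to 4 decimal places as printed
#' in comparison tables (0.05 over 210 comparisons displays as 0.0002, over
#' 6 comparisons as 0.0083).
#'
#' @param alpha familywise significance level.
#' @param m number of comparisons.
#' @return List with `threshold` (full precision) and `display` (rounded).
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 1) {
  if (m < 1) stopf("m must be at least 1")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must lie in (0, 1)")
  th <- alpha / m
  list(threshold = th, display = round(th, 4))
}

#' Pairwise functional comparisons across groups of HRF curves
#'
#' Runs the max-t permutation test for every unordered pair of levels with at
#' least `min_n` curves each, and applies a Bonferroni threshold based on the
#' realized number of comparisons.
#'
#' @param curves matrix of curves (one per row) on a common grid.
#' @param labels factor/character vector of group labels, one per curve.
#' @param min_n smallest per-group sample size admitted to testing.
#' @param alpha familywise significance level.
#' @param n_permutations permutations per test.
#' @param seed base seed; each comparison uses `seed + index`.
#' @return data.frame with columns `group1`, `group2`, `n1`, `n2`, `t_max`,
#'   `p`, `threshold`, `significant`. Empty (with a warning) when no pair is
#'   eligible.
#' @export
compare_groups <- function(curves, labels, min_n = 6, alpha = 0.05,
                           n_permutations = 10000, seed = 1) {
  curves <- as.matrix(curves)
  if (nrow(curves) != length(labels)) stopf("one label per curve required")
  counts <- table(labels)
  lev <- names(counts)[counts >= min_n]
  if (length(lev) < 2) {
    warning("no eligible comparisons (need two groups with n >= ", min_n, ")")
    return(data.frame(group1 = character(0), group2 = character(0),
                      n1 = integer(0), n2 = integer(0), t_max = numeric(0),
                      p = numeric(0), threshold = numeric(0),
                      significant = logical(0)))
  }
  pairs <- utils::combn(lev, 2)
  m <- ncol(pairs)
  th <- bonferroni_threshold(alpha, m)$threshold
  rows <- lapply(seq_len(m), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    r <- max_t_permutation_test(curves[labels == g1, , drop = FALSE],
                                curves[labels == g2, , drop = FALSE],
                                n_permutations = n_permutations,
                                seed = seed + i)
    data.frame(group1 = g1, group2 = g2, n1 = r$n_x, n2 = r$n_y,
               t_max = r$t_max, p = r$p, threshold = th,
               significant = r$p < th)
  })
  do.call(rbind, rows)
}
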