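#' Two-gamma hemodynamic response function parameters
#'
#' Constructs a validated parameter set for the two-gamma HRF model
#' \deqn{HRF(t) = A e^{-bt}\left(\frac{b^{p_1}}{\Gamma(p_1)} t^{p_1-1}
#'   - \frac{b^{p_2}}{V\,\Gamma(p_2)} t^{p_2-1}\right)}
#' in which the first gamma term models the positive BOLD peak and the second
#' the post-stimulus undershoot.
#'
#' @param A amplitude scale (dimensionless after normalization); must be nonzero.
#' @param b dispersion/rate parameter (1/s); must be positive.
#' @param p1 peak shape parameter (dimensionless); must exceed 1 so the
#'   response is zero at `t = 0`.
#' @param p2 undershoot shape parameter; must exceed `p1`.
#' @param V peak-to-undershoot ratio; must be positive.
#' @param species optional species tag carried as metadata.
#'
#' @return An object of class `hrf_params`.
#' @seealso [hrf_preset()], [evaluate_hrf()]
#' @export
#' @examples
#' hrf_params(b = 0.9, p1 = 4.5, p2 = 7.9, V = 1.8, species = "mouse")
hrf_params <- function(A = 1, b, p1, p2, V, species = NA_character_) {
  vals <- c(A = A, b = b, p1 = p1, p2 = p2, V = V)
  if (any(!is.finite(vals))) stopf("HRF parameters must be finite numbers")
  if (A == 0) stopf("invalid HRF parameters: A must be nonzero")
  if (b <= 0) stopf("invalid HRF parameters: b must be positive (got %g)", b)
  if (p1 <= 1) stopf("invalid HRF parameters: p1 must exceed 1 (got %g)", p1)
  if (p2 <= p1) stopf("invalid HRF parameters: p2 (%g) must exceed p1 (%g)", p2, p1)
  if (V <= 0) stopf("invalid HRF parameters: V must be positive (got %g)", V)
  structure(list(A = A, b = b, p1 = p1, p2 = p2, V = V, species = species),
            class = "hrf_params")
}

#' @export
print.hrf_params <- function(x, ...) {
  sp <- if (is.na(x$species)) "" else sprintf(" (%s)", x$species)
  cat(sprintf("Two-gamma HRF parameters%s:\n", sp))
  cat(sprintf("  A = %g, b = %g 1/s, p1 = %g, p2 = %g, V = %g\n",
              x$A, x$b, x$p1, x$p2, x$V))
  invisible(x)
}

#' Species preset HRF parameters
#'
#' `"mouse"` is the whole-brain mouse HRF (b = 0.9, p1 = 4.5, p2 = 7.9,
#' V = 1.8). `"human"` is the standard canonical two-gamma default expressed in
#' this parameterization (b = 1, p1 = 6, p2 = 16, V = 6). Rat parameters are
#' not built in; load them from a parameter file via [read_hrf_params()].
#'
#' @param species `"mouse"` or `"human"`.
#' @return An `hrf_params` object.
#' @export
hrf_preset <- function(species = c("mouse", "human")) {
  species <- match.arg(species)
  switch(species,
    mouse = hrf_params(A = 1, b = 0.9, p1 = 4.5, p2 = 7.9, V = 1.8, species = "mouse"),
    human = hrf_params(A = 1, b = 1, p1 = 6, p2 = 16, V = 6, species = "human")
  )
}

#' Uniform time grid for HRF evaluation
#'
#' @param t_max end of the support (s). The default, 30 s, spans one paradigm
#'   cycle of the 10 s stimulation / 20 s rest block design.
#' @param dt grid spacing (s).
#' @return Numeric vector of times starting at 0.
#' @export
hrf_time_grid <- function(t_max = 30, dt = 0.05) {
  if (t_max <= 0 || dt <= 0) stopf("t_max and dt must be positive")
  seq(0, t_max, by = dt)
}

## raw evaluation of the two-gamma form on arbitrary times (internal)
hrf_eval_raw <- function(times, A, b, p1, p2, V) {
  v <- A * exp(-b * times) *
    (b^p1 / gamma(p1) * times^(p1 - 1) - b^p2 / (V * gamma(p2)) * times^(p2 - 1))
  v[times == 0] <- 0  # t^(p-1) -> 0 as t -> 0+ since p > 1
  v
}

#' Evaluate the two-gamma HRF on a time grid
#'
#' @param params an [hrf_params()] object.
#' @param times uniform time grid starting at 0 (s); see [hrf_time_grid()].
#' @return An object of class `hrf_curve`: a list with elements `time`,
#'   `value` and `params`.
#' @export
#' @examples
#' curve <- evaluate_hrf(hrf_preset("mouse"))
#' characterize_hrf(curve)
evaluate_hrf <- function(params, times = hrf_time_grid()) {
  if (!inherits(params, "hrf_params")) stopf("params must be an hrf_params object")
  if (length(times) == 0) stopf("empty time grid")
  if (times[1] != 0) stopf("time grid must start at 0")
  if (length(times) > 1 && any(diff(times) <= 0)) stopf("time grid must be strictly increasing")
  value <- hrf_eval_raw(times, params$A, params$b, params$p1, params$p2, params$V)
  hrf_curve(times, value, params)
}

#' @rdname evaluate_hrf
#' @param time,value time grid and response values of an existing curve.
#' @export
hrf_curve <- function(time, value, params = NULL) {
  if (length(time) != length(value)) stopf("time and value lengths differ")
  if (any(!is.finite(value))) stopf("curve values must be finite")
  structure(list(time = time, value = value, params = params), class = "hrf_curve")
}

#' @export
print.hrf_curve <- function(x, ...) {
  cat(sprintf("HRF curve: %d points on [%g, %g] s, peak %.4g\n",
              length(x$time), min(x$time), max(x$time), max(x$value)))
  invisible(x)
}

#' Temporal and dispersion derivative basis curves
#'
#' Finite-difference derivative regressors used by the 3rd-order canonical
#' basis: the temporal derivative is the response change under a small onset
#' shift, the dispersion derivative the change under a small relative
#' perturbation of the rate parameter `b`.
#'
#' @inheritParams evaluate_hrf
#' @param shift onset shift (s) for the temporal derivative.
#' @param rel_db relative perturbation of `b` for the dispersion derivative.
#' @return List with `hrf_curve` elements `temporal` and `dispersion`.
#' @export
hrf_basis_derivatives <- function(params, times = hrf_time_grid(),
                                  shift = 0.1, rel_db = 0.01) {
  base <- evaluate_hrf(params, times)
  shifted <- hrf_eval_raw(pmax(times - shift, 0), params$A, params$b,
                          params$p1, params$p2, params$V)
  temporal <- (base$value - shifted) / shift
  pb <- params
  pb$b <- params$b * (1 + rel_db)
  disp <- (hrf_eval_raw(times, pb$A, pb$b, pb$p1, pb$p2, pb$V) - base$value) /
    (params$b * rel_db)
  list(temporal = hrf_curve(times, temporal, params),
       dispersion = hrf_curve(times, disp, params))
}

## interpolated half-maximum crossing between grid points i and i+1
interp_crossing <- function(time, value, i, level) {
  time[i] + (level - value[i]) / (value[i + 1] - value[i]) * (time[i + 1] - time[i])
}

#' Summary kinetics of an HRF curve
#'
#' Computes time to peak, peak value, full width at half maximum (FWHM, with
#' linear interpolation between grid points), time to undershoot (post-peak
#' minimum) and the undershoot value.
#'
#' @param curve an `hrf_curve` with a positive global maximum.
#' @return A list of class `hrf_summary` with elements `time_to_peak`,
#'   `peak_value`, `fwhm`, `time_to_undershoot`, `undershoot_value`.
#' @export
characterize_hrf <- function(curve) {
  stopifnot(inherits(curve, "hrf_curve"))
  v <- curve$value; tt <- curve$time
  ipk <- which.max(v)
  peak <- v[ipk]
  if (peak <= 0) stopf("degenerate curve: no positive peak")
  half <- peak / 2
  above <- which(v >= half)
  i1 <- above[1]; i2 <- above[length(above)]
  left <- if (i1 > 1) interp_crossing(tt, v, i1 - 1, half) else tt[1]
  right <- if (i2 < length(v)) interp_crossing(tt, v, i2, half) else tt[length(v)]
  post <- v[(ipk + 1):length(v)]
  imin <- ipk + which.min(post)
  structure(list(
    time_to_peak = tt[ipk],
    peak_value = peak,
    fwhm = right - left,
    time_to_undershoot = tt[imin],
    undershoot_value = v[imin]
  ), class = "hrf_summary")
}

#' @export
print.hrf_summary <- function(x, ...) {
  cat(sprintf("HRF kinetics: peak %.3g at %.2f s, FWHM %.2f s, undershoot %.3g at %.2f s\n",
              x$peak_value, x$time_to_peak, x$fwhm, x$undershoot_value,
              x$time_to_undershoot))
  invisible(x)
}

#' Normalize a curve to unit maximum
#'
#' @param curve an `hrf_curve` with positive maximum.
#' @return The curve divided by its maximum (peak value 1).
#' @export
normalize_to_max <- function(curve) {
  stopifnot(inherits(curve, "hrf_curve"))
  m <- max(curve$value)
  if (m <= 0) stopf("degenerate curve: non-positive maximum")
  hrf_curve(curve$time, curve$value / m, curve$params)
}

#' Read and write HRF parameter files
#'
#' JSON files with keys `A`, `b`, `p1`, `p2`, `V` plus `species` and `source`
#' metadata, intended for implementing a measured HRF in external GLM software
#' and for loading externally derived parameter sets (e.g. a rat HRF).
#'
#' @param params an `hrf_params` object.
#' @param path file path.
#' @param source free-text provenance string stored in the file.
#' @return `read_hrf_params` returns an `hrf_params` object;
#'   `write_hrf_params` returns `path` invisibly.
#' @export
write_hrf_params <- function(params, path, source = "hrfkit") {
  stopifnot(inherits(params, "hrf_params"))
  out <- list(A = params$A, b = params$b, p1 = params$p1, p2 = params$p2,
              V = params$V, species = params$species, source = source)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_hrf_params
#' @export
read_hrf_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  hrf_params(A = x$A, b = x$b, p1 = x$p1, p2 = x$p2, V = x$V,
             species = x$species %||% NA_character_)
}

#' Sample a set of jittered HRF curves
#'
#' Draws HRF parameter sets around a base parameterization by independent
#' multiplicative lognormal jitter on `b`, `p1`, the gap `p2 - p1` and `V`
#' (so all parameter invariants are preserved), and evaluates each on a
#' common grid. Used for null-calibration experiments where many HRFs from
#' one population are needed.
#'
#' @param n number of curves.
#' @param base an [hrf_params()] object: the population center.
#' @param jitter_sd standard deviation of the lognormal jitter (relative).
#' @param times evaluation grid.
#' @param seed RNG seed.
#' @return Matrix with one curve per row (`n` by `length(times)`).
#' @export
sample_hrf_curves <- function(n, base = hrf_preset("mouse"), jitter_sd = 0.1,
                              times = hrf_time_grid(), seed = 1) {
  withr::with_seed(seed, {
    out <- matrix(0, n, length(times))
    for (i in seq_len(n)) {
      f <- exp(stats::rnorm(4, 0, jitter_sd))
      p <- hrf_params(A = base$A, b = base$b * f[1], p1 = base$p1 * f[2],
                      p2 = base$p1 * f[2] + (base$p2 - base$p1) * f[3],
                      V = base$V * f[4])
      out[i, ] <- evaluate_hrf(p, times)$value
    }
    out
  })
}
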