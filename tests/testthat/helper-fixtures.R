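## shared fixture builders (everything generated in code; no stored data)

## an epoch_curve object from raw values on the standard 30 s / TR 1 s cycle
make_epoch <- function(values, pre_window = 10, TR = 1) {
  structure(list(time = (seq_along(values) - 1) * TR, value = values,
                 n_cycles = 20, n_voxels = 1L, structure = NA,
                 pre_window = pre_window, TR = TR), class = "epoch_curve")
}

## a noise-free mouse-HRF epoch curve under the default acquisition
mouse_epoch_curve <- function(amplitude = 1, paradigm = block_paradigm()) {
  pred <- epoch_predictor(paradigm)
  p <- hrf_preset("mouse")
  vals <- pred(c(p$A, p$b, p$p1, p$p2 - p$p1, p$V))
  make_epoch(amplitude * vals / max(vals), pre_window = paradigm$pre_window,
             TR = paradigm$TR)
}

## small noise-free synthetic dataset shared by detection/pipeline tests
tiny_noisefree_spec <- function(seed = 3, ...) {
  synthetic_spec(dims = c(16, 16, 8), n_structures = 8, noise_sd = 0,
                 response_amplitude_sd = 0, seed = seed, ...)
}

## log-gamma arithmetic oracle for the two-gamma HRF (independent of
## hrf_eval_raw's direct gamma/power arithmetic)
hrf_oracle_loggamma <- function(t, A, b, p1, p2, V) {
  out <- numeric(length(t))
  pos <- t > 0
  lt <- log(t[pos])
  term1 <- exp(p1 * log(b) - lgamma(p1) + (p1 - 1) * lt)
  term2 <- exp(p2 * log(b) - lgamma(p2) + (p2 - 1) * lt) / V
  out[pos] <- A * exp(-b * t[pos]) * (term1 - term2)
  out
}
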