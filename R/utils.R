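## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

## FFT linear convolution of two vectors, padded to a power of two.
## Returns the first `n_out` samples of the full convolution, scaled by `dt`
## so that it approximates the continuous-time integral.
fft_convolve <- function(x, y, dt = 1, n_out = length(x)) {
  n <- length(x) + length(y) - 1L
  nf <- stats::nextn(n, 2)
  xf <- stats::fft(c(x, rep(0, nf - length(x))))
  yf <- stats::fft(c(y, rep(0, nf - length(y))))
  out <- Re(stats::fft(xf * yf, inverse = TRUE)) / nf
  out[seq_len(n_out)] * dt
}

## near-equality for grid spacings
near <- function(a, b, tol = 1e-8) abs(a - b) < tol

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## write a data.frame as TSV without quoting/rownames
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

## md5 of an R object via its canonical JSON serialization (for provenance)
object_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tf))
}

## linear index <-> (i,j,k) for a 3D array, and 6-neighbourhood shifts
array_neighbors6 <- function(idx, dims) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  k <- (idx - 1L) %/% (nx * ny)
  r <- (idx - 1L) %% (nx * ny)
  j <- r %/% nx
  i <- r %% nx
  out <- list(
    ifelse(i > 0L, idx - 1L, NA_integer_),
    ifelse(i < nx - 1L, idx + 1L, NA_integer_),
    ifelse(j > 0L, idx - nx, NA_integer_),
    ifelse(j < ny - 1L, idx + nx, NA_integer_),
    ifelse(k > 0L, idx - nx * ny, NA_integer_),
    ifelse(k < nz - 1L, idx + nx * ny, NA_integer_)
  )
  out
}

## connected components (6-neighbourhood) of a logical 3D array.
## Returns an integer array: 0 outside, component id inside.
label_components6 <- function(mask) {
  dims <- dim(mask)
  stopifnot(length(dims) == 3L)
  active <- which(mask)
  lab <- array(0L, dims)
  if (length(active) == 0L) return(lab)
  pos <- integer(prod(dims))
  pos[active] <- seq_along(active)
  nb <- array_neighbors6(active, dims)
  edges <- integer(0)
  for (d in seq_along(nb)) {
    to <- nb[[d]]
    ok <- !is.na(to) & to > 0
    ok[ok] <- pos[to[ok]] > 0L
    if (any(ok)) edges <- c(edges, rbind(pos[active[ok]], pos[to[ok]]))
  }
  g <- igraph::make_graph(edges = edges, n = length(active), directed = FALSE)
  comp <- igraph::components(g)
  lab[active] <- comp$membership
  lab
}
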