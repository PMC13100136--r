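# FFT bookkeeping helpers. Grids are stored DC-centered for inspection and
# moved to corner (FFT) order only around transform calls.

#' Frequency sample points for a discrete Fourier transform axis
#'
#' @param n number of samples
#' @param d sample spacing (e.g. nm); frequencies are in cycles per unit of `d`
#' @return numeric vector of length `n` in FFT (corner) order
#' @keywords internal
fft_freq <- function(n, d = 1) {
  c(seq.int(0L, ceiling(n / 2) - 1L), seq.int(-floor(n / 2), -1L)) / (n * d)
}

# circular shift: element i moves to position i + s (mod n) along each axis
nd_roll <- function(x, shift) {
  d <- dim(x)
  if (is.null(d)) {
    n <- length(x)
    s <- shift[1L] %% n
    if (s == 0) return(x)
    return(x[((seq_len(n) - 1L - s) %% n) + 1L])
  }
  stopifnot(length(shift) == length(d))
  idx <- lapply(seq_along(d), function(k) {
    s <- shift[k] %% d[k]
    ((seq_len(d[k]) - 1L - s) %% d[k]) + 1L
  })
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

# DC (index 1) -> center index floor(n/2)+1
fftshift <- function(x) {
  d <- if (is.null(dim(x))) length(x) else dim(x)
  nd_roll(x, floor(d / 2))
}

# inverse of fftshift (center -> index 1)
ifftshift <- function(x) {
  d <- if (is.null(dim(x))) length(x) else dim(x)
  nd_roll(x, -floor(d / 2))
}

# sample array at k + shift (corner-order frequency arrays, integer bins);
# result[k] = x[k + shift]
shift_spectrum <- function(x, shift) nd_roll(x, -as.integer(shift))

# spectrum of the complex conjugate: k -> -k reflection in corner order
flip_spectrum <- function(x) {
  d <- dim(x)
  idx <- lapply(d, function(n) c(1L, rev(seq_len(n)[-1L])))
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

ifft <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# centered crop in corner-order space: source index for centered output index j
crop_index <- function(n_out, n_in) {
  (((seq_len(n_out) - (floor(n_out / 2) + 1L)) %% n_in) + 1L)
}
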