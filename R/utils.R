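# Internal numeric helpers shared across modules.

# DFT sample frequencies for n samples at spacing d (same ordering as the
# unshifted output of stats::fft): 0, 1, ..., then the negative branch.
fft_freq <- function(n, d = 1) {
  k <- 0L:(n - 1L)
  k[k > (n - 1L) %/% 2L] <- k[k > (n - 1L) %/% 2L] - n
  k / (n * d)
}

# Index permutation moving the zero-frequency bin to position
# floor(n/2) + 1 (DC-centred grid).
fftshift_index <- function(n) {
  s <- ceiling(n / 2)
  c((s + 1L):n, 1L:s)
}

ifftshift_index <- function(n) {
  s <- floor(n / 2)
  c((s + 1L):n, 1L:s)
}

fftshift2 <- function(m) m[fftshift_index(nrow(m)), fftshift_index(ncol(m))]

ifftshift2 <- function(m) m[ifftshift_index(nrow(m)), ifftshift_index(ncol(m))]

# First downward crossing of `level` on a curve sampled at (x, y), by linear
# interpolation; returns max(x) when the curve never falls below the level.
first_down_crossing <- function(x, y, level) {
  below <- which(y < level)
  below <- below[below > 1L]
  if (length(below) == 0L) {
    return(max(x))
  }
  i <- below[1L]
  x0 <- x[i - 1L]; y0 <- y[i - 1L]
  x1 <- x[i]; y1 <- y[i]
  if (y0 == y1) {
    return(x0)
  }
  x0 + (level - y0) * (x1 - x0) / (y1 - y0)
}

# Moving median with odd window k (edges use shrunken windows).
moving_median <- function(x, k = 7L) {
  n <- length(x)
  if (n == 0L || k <= 1L) {
    return(x)
  }
  h <- k %/% 2L
  vapply(seq_len(n), function(i) {
    stats::median(x[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
}

# Smooth step used by the simulator: Gaussian-blurred Heaviside.
blurred_step <- function(t, sigma) {
  if (sigma <= 0) {
    as.numeric(t >= 0)
  } else {
    stats::pnorm(t / sigma)
  }
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
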