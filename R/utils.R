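# Internal numeric helpers shared across the package.

# DC-centred frequency coordinates for an n-point DFT, in cycles/pixel.
# After fftshift the DC bin sits at index floor(n/2) + 1.
centered_freqs <- function(n) {
  (seq_len(n) - 1L - floor(n / 2)) / n
}

# Unshifted DFT frequency coordinates with wraparound (bin k -> k/n mapped
# into [-0.5, 0.5)).
wrapped_freqs <- function(n) {
  f <- (seq_len(n) - 1L) / n
  f[f >= 0.5] <- f[f >= 0.5] - 1
  f
}

# Index permutation that moves DC (index 1) to floor(n/2) + 1.
fftshift_idx <- function(n) {
  h <- floor(n / 2)
  c((n - h + 1L):n, 1L:(n - h))
}

ifftshift_idx <- function(n) {
  order(fftshift_idx(n))
}

fftshift2 <- function(m) {
  m[fftshift_idx(nrow(m)), fftshift_idx(ncol(m)), drop = FALSE]
}

ifftshift2 <- function(m) {
  m[ifftshift_idx(nrow(m)), ifftshift_idx(ncol(m)), drop = FALSE]
}

# 1D Tukey (tapered cosine) window of length n with taper fraction a in
# [0, 1]; a = 0 is rectangular, a = 1 is Hann.
tukey_window <- function(n, a) {
  stopifnot(n >= 1, a >= 0, a <= 1)
  if (n == 1L) return(1)
  x <- (seq_len(n) - 1) / (n - 1)
  w <- rep(1, n)
  if (a > 0) {
    lo <- x < a / 2
    hi <- x > 1 - a / 2
    w[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / a - 1)))
    w[hi] <- 0.5 * (1 + cos(pi * (2 * x[hi] / a - 2 / a + 1)))
  }
  w
}

# Scaled complementary error function exp(x^2) * erfc(x), stable for large
# positive x where the naive product overflows. Vectorised.
erfcx_stable <- function(x) {
  out <- numeric(length(x))
  big <- x > 25
  if (any(!big)) out[!big] <- pracma::erfcx(x[!big])
  if (any(big)) {
    # asymptotic series 1/(x sqrt(pi)) * (1 - 1/(2x^2) + 3/(4x^4) - 15/(8x^6))
    z <- x[big]
    iz2 <- 1 / (2 * z^2)
    out[big] <- (1 - iz2 * (1 - 3 * iz2 * (1 - 5 * iz2))) / (z * sqrt(pi))
  }
  out
}

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("framecodec_validation", "error")))
}

stop_infeasible <- function(...) {
  stop(errorCondition(paste0(...), class = c("framecodec_infeasible", "error")))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
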