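# Shared fixture generators and independent oracles. Fixtures are built in
# code at test time; oracles deliberately avoid the code paths they check.

# Gaussian low-pass filtered white noise: smooth random image with spectral
# content confined below ~3*cutoff (cycles/pixel).
lowpass_noise <- function(n, cutoff) {
  f <- framecodec:::wrapped_freqs(n)
  h <- exp(-outer(f^2, f^2, "+") / (2 * cutoff^2))
  img <- Re(stats::fft(stats::fft(matrix(stats::runif(n * n), n, n)) * h,
                       inverse = TRUE)) / n^2
  img <- img - min(img)
  img / max(img)
}

# Band-limited smooth test frame that vignettes to zero at the borders
# (real beam images are dark at the field edges; an abrupt border would put
# wraparound leakage ridges through the whole spectrum).
smooth_test_frame <- function(n, cutoff = 0.005, edge_taper = 0.5,
                              pitch = 1) {
  tp <- framecodec:::tukey_window(n, edge_taper)
  frame(lowpass_noise(n, cutoff) * (tp %o% tp), pixel_pitch = pitch)
}

# Direct two-loop 2D DFT, DC-centred: the brute-force oracle for spectrum
# examples. O(N^4); keep images small.
dft2_loop <- function(img) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0 + 0i, h, w)
  for (ki in seq_len(h)) {
    for (kj in seq_len(w)) {
      ky <- ki - 1L; kx <- kj - 1L
      ph <- outer((0:(h - 1)) * ky / h, (0:(w - 1)) * kx / w, "+")
      out[ki, kj] <- sum(img * exp(-2i * pi * ph))
    }
  }
  framecodec:::fftshift2(out)
}

# Direct spatial lock-in: demodulate by the complex carrier, circularly
# convolve with the window's spatial kernel (itself built by a direct
# inverse DFT), scale by 2/m and take the modulus. Avoids fft() entirely.
spatial_lockin_oracle <- function(img, carrier, filt, m) {
  h <- nrow(img); w <- ncol(img)
  fx <- framecodec:::wrapped_freqs(w)
  fy <- framecodec:::wrapped_freqs(h)
  win <- framecodec:::filter_response(filt, sqrt(outer(fy^2, fx^2, "+")))
  ker <- matrix(0 + 0i, h, w)
  for (u in 0:(h - 1)) {
    for (v in 0:(w - 1)) {
      ph <- outer((0:(h - 1)) * u / h, (0:(w - 1)) * v / w, "+")
      ker[u + 1, v + 1] <- sum(win * exp(2i * pi * ph)) / (h * w)
    }
  }
  xs <- 0:(w - 1); ys <- 0:(h - 1)
  d <- img * exp(-1i * (outer(2 * pi * carrier[2] * ys,
                              2 * pi * carrier[1] * xs, "+")))
  conv <- matrix(0 + 0i, h, w)
  for (y in 0:(h - 1)) {
    for (x in 0:(w - 1)) {
      conv[y + 1, x + 1] <- sum(d * ker[((y - ys) %% h) + 1,
                                        ((x - xs) %% w) + 1])
    }
  }
  pmax((2 / m) * Mod(conv), 0)
}

# Conjugate-aware pairwise separation check by exhaustive enumeration.
min_pair_separation <- function(nu) {
  n <- nrow(nu)
  if (n < 2) return(Inf)
  best <- Inf
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      for (si in c(1, -1)) {
        for (sj in c(1, -1)) {
          best <- min(best, sqrt(sum((si * nu[i, ] - sj * nu[j, ])^2)))
        }
      }
    }
  }
  best
}

# Intensity centroid of a 1D profile, in pixel units (1-based centres).
profile_centroid <- function(p) sum(p * seq_along(p)) / sum(p)

# Default light-in-flight scene: CS2 cell probed on a detector-scale x grid
# (1002 px over 7 mm), pump along +x, read along +z.
lif_scene <- function(nx = 1002, ny = 32, nz = 256, tau = 0,
                      fwhm = 125, waist = 0.25) {
  ext <- c(7, 7, 1.4)
  v <- speed_in_medium(1.63)
  list(
    pump = pulse_spec(fwhm, t0 = 0, direction = c(1, 0, 0), speed = v,
                      waist = waist),
    read = pulse_spec(fwhm, direction = c(0, 0, 1), speed = v),
    medium = kerr_medium(1.63, tau_relax = tau, extent = ext),
    grid = grid_spec(c(nx, ny, nz), ext / c(nx, ny, nz)),
    v = v,
    # read delay that centres the streak at pump position x_mm
    delay_for_x = function(x_mm) x_mm / v - (ext[3] / 2) / v
  )
}
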