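#' Reciprocal-space band-pass filter
#'
#' The region of reciprocal space isolated around one carrier before
#' demodulation. The radius sets the decoded frame's spatial resolution; the
#' window shape trades passband flatness against stopband leakage:
#' `"gaussian"` (default, sigma = `window_param * radius`, truncated at
#' 3 sigma), `"tukey"` (radially flat over `(1 - window_param)` of the
#' radius, cosine-tapered to zero at the radius), or `"hard"` (ideal disk).
#' All windows have unit gain at their centre.
#'
#' @param center 2-vector carrier frequency in cycles/pixel.
#' @param radius filter radius in cycles/pixel (> 0); the disk must stay
#'   inside Nyquist, `|center| + radius <= 0.5`.
#' @param window `"gaussian"`, `"tukey"` or `"hard"`.
#' @param window_param Gaussian sigma as a fraction of the radius (default
#'   0.5), or the Tukey taper fraction (default 0.5). Ignored for `"hard"`.
#' @return An object of class `band_filter`.
#' @export
band_filter <- function(center, radius, window = c("gaussian", "tukey", "hard"),
                        window_param = NULL) {
  window <- match.arg(window)
  if (!is.numeric(center) || length(center) != 2L || any(!is.finite(center)))
    stop_validation("'center' must be a finite numeric 2-vector")
  if (!is_scalar_number(radius) || radius <= 0)
    stop_validation("'radius' must be positive (cycles/pixel)")
  if (sqrt(sum(center^2)) + radius > 0.5 + 1e-12)
    stop_validation("filter extends beyond Nyquist: |center| + radius > 0.5")
  if (is.null(window_param)) window_param <- 0.5
  if (!is_scalar_number(window_param) || window_param <= 0 || window_param > 1)
    stop_validation("'window_param' must lie in (0, 1]")
  structure(list(center = as.numeric(center), radius = radius,
                 window = window, window_param = window_param),
            class = "band_filter")
}

# Unit-peak radial frequency response of a band filter, evaluated at radial
# distances rho (cycles/pixel) from the filter centre.
filter_response <- function(filt, rho) {
  r <- filt$radius
  switch(filt$window,
    gaussian = {
      sigma <- filt$window_param * r
      w <- exp(-rho^2 / (2 * sigma^2))
      w[rho > 3 * sigma] <- 0
      w
    },
    tukey = {
      a <- filt$window_param
      flat <- (1 - a) * r
      w <- numeric(length(rho))
      w[rho <= flat] <- 1
      tp <- rho > flat & rho < r
      w[tp] <- 0.5 * (1 + cos(pi * (rho[tp] - flat) / (r - flat)))
      w
    },
    hard = as.numeric(rho <= r)
  )
}

#' DC-centred 2D Fourier spectrum of an image
#'
#' Computes the 2D discrete Fourier transform of a frame or exposure and
#' re-centres it so DC sits in the middle of the array. Optional
#' pre-apodisation (separable Tukey window, taper 0.2) suppresses the
#' spectral leakage of image borders; optional mean subtraction removes the
#' dominant DC peak, which is useful before carrier detection.
#'
#' @param x a [frame()], [compose()] exposure, or numeric matrix.
#' @param apodize apply a Tukey taper to the image before transforming.
#' @param taper Tukey taper fraction used when `apodize = TRUE`.
#' @param subtract_mean subtract the image mean before transforming.
#' @return An object of class `spectrum2d`: `values` (complex matrix,
#'   DC-centred), `fx` (column frequencies) and `fy` (row frequencies), both
#'   in cycles/pixel.
#' @examples
#' sp <- image_spectrum(frame(matrix(1, 16, 16)))
#' which(Mod(sp$values) > 1e-9, arr.ind = TRUE)  # single DC bin at (9, 9)
#' @export
image_spectrum <- function(x, apodize = FALSE, taper = 0.2,
                           subtract_mean = FALSE) {
  px <- pixel_matrix(x) * 1.0
  if (any(!is.finite(px))) stop_validation("image contains non-finite values")
  if (subtract_mean) px <- px - mean(px)
  if (apodize) {
    px <- px * (tukey_window(nrow(px), taper) %o% tukey_window(ncol(px), taper))
  }
  v <- fftshift2(stats::fft(px))
  structure(list(values = v,
                 fx = centered_freqs(ncol(px)),
                 fy = centered_freqs(nrow(px))),
            class = "spectrum2d")
}

#' @export
print.spectrum2d <- function(x, ...) {
  cat(sprintf("<spectrum2d> %d x %d bins, DC-centred, |F| range [%.4g, %.4g]\n",
              nrow(x$values), ncol(x$values), min(Mod(x$values)),
              max(Mod(x$values))))
  invisible(x)
}

#' Display the log-magnitude of a 2D spectrum
#'
#' @param x a `spectrum2d`.
#' @param main plot title.
#' @param ... passed to [graphics::image()].
#' @export
plot.spectrum2d <- function(x, main = "log10 |F|", ...) {
  a <- log10(Mod(x$values) + 1e-12 * max(Mod(x$values)))
  graphics::image(x$fx, rev(-x$fy), t(a[nrow(a):1, , drop = FALSE]),
                  col = grDevices::hcl.colors(256, "viridis"),
                  xlab = expression(nu[x] ~ "(cycles/pixel)"),
                  ylab = expression(nu[y] ~ "(cycles/pixel)"),
                  main = main, useRaster = TRUE, ...)
  invisible(x)
}

#' Locate carrier peaks in a spectrum
#'
#' Finds the `n_expected` strongest isolated sideband peaks in the upper
#' half-plane of reciprocal space (one per conjugate pair), outside a DC
#' exclusion disk, and refines each location to sub-bin precision with a
#' 3 x 3 intensity centroid. When `x` is an image rather than a spectrum it
#' is transformed with mean subtraction and apodisation first (taper 0.2),
#' which keeps baseband sidelobes from masquerading as carriers.
#'
#' A candidate peak must be a local maximum exceeding both 5 times the
#' median spectral magnitude and `1e-9` times the spectral maximum (the
#' absolute guard rejects numerical noise on an otherwise empty spectrum).
#'
#' @param x a `spectrum2d`, or a frame/exposure/matrix to transform.
#' @param n_expected number of carriers to recover (>= 1).
#' @param exclusion_r0 DC exclusion radius in cycles/pixel.
#' @return An `n_expected` x 2 matrix of `(nu_x, nu_y)` frequencies, sorted
#'   by descending peak magnitude.
#' @export
detect_carriers <- function(x, n_expected, exclusion_r0 = 0.05) {
  if (!is_scalar_number(n_expected) || n_expected < 1)
    stop_validation("'n_expected' must be >= 1")
  n_expected <- as.integer(n_expected)
  sp <- if (inherits(x, "spectrum2d")) x
        else image_spectrum(x, apodize = TRUE, subtract_mean = TRUE)
  a <- Mod(sp$values)
  h <- nrow(a); w <- ncol(a)
  fx <- matrix(sp$fx, h, w, byrow = TRUE)
  fy <- matrix(sp$fy, h, w)
  rho <- sqrt(fx^2 + fy^2)
  upper <- fy > 0 | (fy == 0 & fx > 0)

  # strict local maxima over the 8-neighbourhood (border excluded)
  is_max <- matrix(FALSE, h, w)
  ii <- 2:(h - 1); jj <- 2:(w - 1)
  core <- a[ii, jj]
  is_max[ii, jj] <-
    core >= a[ii - 1, jj] & core >= a[ii + 1, jj] &
    core >= a[ii, jj - 1] & core >= a[ii, jj + 1] &
    core >= a[ii - 1, jj - 1] & core >= a[ii - 1, jj + 1] &
    core >= a[ii + 1, jj - 1] & core >= a[ii + 1, jj + 1] &
    core > 0
  thr <- max(5 * stats::median(a), 1e-9 * max(a))
  cand <- which(is_max & upper & rho > exclusion_r0 & a > thr, arr.ind = TRUE)
  if (nrow(cand) > 0) {
    ord <- order(a[cand], decreasing = TRUE)
    cand <- cand[ord, , drop = FALSE]
    # suppress secondary maxima on the shoulder of an accepted peak
    keep <- logical(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      if (!any(keep)) { keep[k] <- TRUE; next }
      prev <- cand[keep, , drop = FALSE]
      d2 <- (prev[, 1] - cand[k, 1])^2 + (prev[, 2] - cand[k, 2])^2
      keep[k] <- all(d2 > 9)   # > 3 bins away from every accepted peak
    }
    cand <- cand[keep, , drop = FALSE]
  }
  if (nrow(cand) < n_expected)
    stop_validation("carriers not found: expected ", n_expected,
                    " peaks above threshold, found ", nrow(cand))
  cand <- cand[seq_len(n_expected), , drop = FALSE]

  out <- matrix(0, n_expected, 2, dimnames = list(NULL, c("nu_x", "nu_y")))
  for (k in seq_len(n_expected)) {
    i <- cand[k, 1]; j <- cand[k, 2]
    wi <- a[(i - 1):(i + 1), (j - 1):(j + 1)]
    sx <- sp$fx[(j - 1):(j + 1)]
    sy <- sp$fy[(i - 1):(i + 1)]
    out[k, 1] <- sum(wi %*% sx) / sum(wi)
    out[k, 2] <- sum(sy %*% wi) / sum(wi)
  }
  out
}

#' Extract one frame from a multiplexed exposure
#'
#' The frequency-sensitive spatial lock-in of the codec: the exposure is
#' demodulated by the complex carrier `exp(-2*pi*i * nu . x)` — an exact
#' transfer of the `+nu` sideband to the origin of reciprocal space, valid
#' also for carriers that do not fall on an integer DFT bin — then low-pass
#' filtered with the band filter's window (now centred at DC), inverse
#' transformed, and scaled by `2/m`. The modulus of the complex result is
#' taken, which makes the decode insensitive to the unknown absolute fringe
#' phase. Output is clipped at zero.
#'
#' @param exposure a [compose()] exposure, [frame()], or matrix.
#' @param carrier 2-vector carrier frequency (cycles/pixel).
#' @param filt a [band_filter()] whose centre equals `carrier`.
#' @param m modulation depth used at encode, in (0, 1].
#' @param gain DN per input intensity unit; decoded pixels are divided by
#'   it. Defaults to the exposure's recorded auto-exposure gain when
#'   available (synthetic pipeline), else 1.
#' @return A `frame` with the same shape as the exposure.
#' @export
extract_frame <- function(exposure, carrier, filt, m = 1, gain = NULL) {
  if (!inherits(filt, "band_filter"))
    stop_validation("'filt' must be a band_filter")
  if (!is.numeric(carrier) || length(carrier) != 2L)
    stop_validation("'carrier' must be a numeric 2-vector")
  if (max(abs(filt$center - carrier)) > 1e-9)
    stop_validation("filter centre must equal the carrier frequency")
  if (!is_scalar_number(m) || m <= 0 || m > 1)
    stop_validation("'m' must lie in (0, 1]")
  if (sqrt(sum(carrier^2)) + filt$radius > 0.5 + 1e-12)
    stop_validation("filter extends beyond Nyquist")
  if (is.null(gain))
    gain <- if (inherits(exposure, "multiplexed_exposure")) exposure$gain else 1
  px <- pixel_matrix(exposure) * 1.0
  h <- nrow(px); w <- ncol(px)
  xs <- 0:(w - 1L); ys <- 0:(h - 1L)
  ph <- outer(2 * pi * carrier[2] * ys, 2 * pi * carrier[1] * xs, "+")
  demod <- px * exp(-1i * ph)
  spec <- stats::fft(demod)
  fx <- matrix(wrapped_freqs(w), h, w, byrow = TRUE)
  fy <- matrix(wrapped_freqs(h), h, w)
  win <- filter_response(filt, sqrt(fx^2 + fy^2))
  out <- Mod(stats::fft(spec * win, inverse = TRUE)) / (h * w) * (2 / m) / gain
  frame(out, pixel_pitch = pitch_of(exposure))
}

#' Decode all frames of a multiplexed exposure
#'
#' Applies [extract_frame()] once per carrier, in codebook order (the
#' temporal order of the read pulses).
#'
#' @param exposure a [compose()] exposure (or frame/matrix).
#' @param cb a [codebook()]; defaults to the codebook stored on the
#'   exposure.
#' @param window,window_param band filter shape, see [band_filter()].
#' @param gain see [extract_frame()].
#' @return List of decoded `frame` objects, one per carrier.
#' @examples
#' cb <- codebook(list(carrier_code(c(0.25, 0)), carrier_code(c(0, 0.25))),
#'                filter_radius = 0.06)
#' fr <- list(frame(matrix(runif(32 * 32), 32, 32) + 1),
#'            frame(matrix(1, 32, 32)))
#' ex <- compose(fr, cb, sensor_model())
#' dec <- demultiplex(ex)
#' length(dec)
#' @export
demultiplex <- function(exposure, cb = NULL,
                        window = c("gaussian", "tukey", "hard"),
                        window_param = NULL, gain = NULL) {
  window <- match.arg(window)
  if (is.null(cb)) {
    if (inherits(exposure, "multiplexed_exposure")) cb <- exposure$codebook
    else stop_validation("'cb' is required when the exposure carries no codebook")
  }
  if (!inherits(cb, "codebook")) stop_validation("'cb' must be a codebook")
  lapply(seq_along(cb$codes), function(i) {
    code <- cb$codes[[i]]
    tryCatch({
      filt <- band_filter(code$nu, cb$filter_radius, window = window,
                          window_param = window_param)
      extract_frame(exposure, code$nu, filt, m = code$m, gain = gain)
    }, error = function(e)
      stop_validation("frame ", i, ": ", conditionMessage(e)))
  })
}
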