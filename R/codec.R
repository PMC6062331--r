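#' Camera sensor model for the multiplexing stage
#'
#' Describes the detector that integrates all modulated frames in one
#' exposure: ADC bit depth, full-well capacity in electrons, RMS Gaussian
#' read noise, optional Poisson shot noise, and the RNG seed that makes a
#' noisy exposure reproducible.
#'
#' @param bit_depth ADC bits, one of 8, 12, 14, 16.
#' @param full_well full-well capacity in electrons (> 0).
#' @param read_noise_sigma RMS read noise in electrons (>= 0).
#' @param shot_noise logical; apply Poisson shot noise in electrons.
#' @param seed integer RNG seed used whenever noise is drawn.
#' @return An object of class `sensor_model`.
#' @export
sensor_model <- function(bit_depth = 16, full_well = 3e4,
                         read_noise_sigma = 0, shot_noise = FALSE,
                         seed = 1L) {
  if (!bit_depth %in% c(8, 12, 14, 16))
    stop_validation("'bit_depth' must be one of 8, 12, 14, 16")
  if (!is_scalar_number(full_well) || full_well <= 0)
    stop_validation("'full_well' must be positive (electrons)")
  if (!is_scalar_number(read_noise_sigma) || read_noise_sigma < 0)
    stop_validation("'read_noise_sigma' must be nonnegative (electrons)")
  if (!is.logical(shot_noise) || length(shot_noise) != 1L)
    stop_validation("'shot_noise' must be TRUE or FALSE")
  if (!is_scalar_number(seed) || abs(seed) >= 2^31)
    stop_validation("'seed' must be a 32-bit integer")
  structure(list(bit_depth = as.integer(bit_depth), full_well = full_well,
                 read_noise_sigma = read_noise_sigma,
                 shot_noise = shot_noise, seed = as.integer(seed)),
            class = "sensor_model")
}

#' Superimpose a sinusoidal carrier on a frame
#'
#' Applies the nonnegative fringe illumination
#' `out(x, y) = in(x, y) * (1 + m * cos(2*pi*(nu_x*x + nu_y*y) + phi))`,
#' with `x` the 0-based column index and `y` the 0-based row index. In
#' reciprocal space this places a scaled copy of the frame's spectrum at
#' `+nu` and `-nu` (amplitude `m/2` each) next to the unmodulated baseband
#' copy. No renormalisation by `(1 + m)` is applied; the decoder restores
#' amplitude with the factor `2/m`.
#'
#' @param frm a [frame()] (or matrix).
#' @param code a [carrier_code()].
#' @return A `frame` of the same shape.
#' @examples
#' f <- frame(matrix(1, 16, 16))
#' g <- modulate(f, carrier_code(c(1/8, 0), m = 1))
#' g$pixels[1, 1:5]   # cosine peaks at column 0, zero at column 4
#' @export
modulate <- function(frm, code) {
  frm <- as_frame(frm)
  if (!inherits(code, "carrier_code"))
    stop_validation("'code' must be a carrier_code")
  px <- frm$pixels
  h <- nrow(px); w <- ncol(px)
  xs <- 0:(w - 1L); ys <- 0:(h - 1L)
  # phase(x,y) = 2 pi (nu_x x + nu_y y) + phi, separable outer sum
  ph <- outer(2 * pi * code$nu[2] * ys, 2 * pi * code$nu[1] * xs, "+") + code$phi
  out <- px * (1 + code$m * cos(ph))
  out[out < 0] <- 0  # guard against -eps from floating cancellation
  frame(out, pixel_pitch = frm$pixel_pitch, time_tag = frm$time_tag)
}

# Internal: analog (pre-sensor) multiplex sum used by compose() and by the
# linearity property tests. No scaling, no noise, no quantisation.
compose_analog <- function(frames, cb) {
  frames <- lapply(frames, as_frame)
  if (length(frames) != length(cb$codes))
    stop_validation("number of frames (", length(frames),
                    ") must equal number of carriers (", length(cb$codes), ")")
  d <- dim(frames[[1]]$pixels)
  s <- matrix(0, d[1], d[2])
  for (i in seq_along(frames)) {
    if (!identical(dim(frames[[i]]$pixels), d))
      stop_validation("frame ", i, " shape differs from frame 1")
    s <- s + modulate(frames[[i]], cb$codes[[i]])$pixels
  }
  s
}

#' Compose modulated frames into one sensor exposure
#'
#' The forward model of the codec: each frame is modulated with its carrier,
#' the modulated frames are summed, the sum is auto-exposed so its maximum
#' maps to the sensor's full well, optional Poisson shot noise and Gaussian
#' read noise are applied in electrons, and the result is quantised to the
#' ADC bit depth by clipping to the full well followed by floor (ADC
#' truncation). All frames share the sensor's dynamic range: `N` spatially
#' overlapping frames on a `B`-bit sensor each keep roughly `B - log2(N)`
#' bits (see [effective_bit_depth()]).
#'
#' Noise draws are seeded from `sensor$seed` and leave the caller's RNG
#' state untouched, so identical inputs give a bit-identical exposure.
#'
#' @param frames list of equally-shaped [frame()] objects, one per carrier.
#' @param cb a [codebook()] with as many carriers as there are frames.
#' @param sensor a [sensor_model()].
#' @return An object of class `multiplexed_exposure`: integer pixels in
#'   `[0, 2^B - 1]`, plus the codebook, sensor, pixel pitch, and the scalar
#'   `gain` (DN per input intensity unit) implied by the auto-exposure,
#'   which the synthetic decode pipeline may use to restore input units.
#' @examples
#' cb <- codebook(list(carrier_code(c(0.2, 0))), filter_radius = 0.04)
#' ex <- compose(list(frame(matrix(1, 32, 32))), cb, sensor_model())
#' max(ex$pixels)  # 65535: the exposure fills the ADC range
#' @export
compose <- function(frames, cb, sensor = sensor_model()) {
  if (!inherits(cb, "codebook")) stop_validation("'cb' must be a codebook")
  if (!inherits(sensor, "sensor_model"))
    stop_validation("'sensor' must be a sensor_model")
  if (length(frames) < 1L) stop_validation("'frames' must not be empty")
  s <- compose_analog(frames, cb)
  smax <- max(s)
  if (smax <= 0) stop_validation("composed exposure is identically zero")
  levels <- 2^sensor$bit_depth - 1
  ratio <- s / smax                       # exactly 1 at the brightest pixel
  electrons <- ratio * sensor$full_well
  if (sensor$shot_noise || sensor$read_noise_sigma > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(sensor$seed)
    if (sensor$shot_noise)
      electrons[] <- stats::rpois(length(electrons), lambda = electrons)
    if (sensor$read_noise_sigma > 0)
      electrons <- electrons +
        stats::rnorm(length(electrons), sd = sensor$read_noise_sigma)
  }
  electrons[electrons < 0] <- 0
  electrons[electrons > sensor$full_well] <- sensor$full_well
  dn <- floor(electrons / sensor$full_well * levels)
  structure(list(pixels = dn, codebook = cb, sensor = sensor,
                 pixel_pitch = pitch_of(frames[[1]]),
                 gain = levels / smax),
            class = "multiplexed_exposure")
}

#' @export
dim.multiplexed_exposure <- function(x) dim(x$pixels)

#' @export
print.multiplexed_exposure <- function(x, ...) {
  cat(sprintf("<multiplexed exposure> %d x %d px, %d-bit, %d carriers, DN range [%d, %d]\n",
              nrow(x$pixels), ncol(x$pixels), x$sensor$bit_depth,
              length(x$codebook$codes), min(x$pixels), max(x$pixels)))
  invisible(x)
}
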