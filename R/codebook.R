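#' Sinusoidal carrier code for one frame
#'
#' A carrier code describes the sinusoidal spatial modulation superimposed on
#' one frame before summation onto the sensor: a 2-vector spatial frequency
#' `nu` (cycles/pixel, each sideband lands at +nu and -nu in reciprocal
#' space), a modulation depth `m` (fringe contrast), and a phase `phi` at
#' pixel (0, 0).
#'
#' @param nu numeric 2-vector `(nu_x, nu_y)` in cycles/pixel; `|nu|` must lie
#'   in (0, 0.5] (Nyquist limit).
#' @param m modulation depth in (0, 1]. A zero depth is rejected: it would
#'   place no sideband in reciprocal space and the frame could never be
#'   recovered.
#' @param phi phase in radians, reduced into `[0, 2*pi)`.
#' @return An object of class `carrier_code`.
#' @examples
#' carrier_code(c(0.2, 0.1), m = 0.8)
#' @export
carrier_code <- function(nu, m = 1, phi = 0) {
  if (!is.numeric(nu) || length(nu) != 2L || any(!is.finite(nu)))
    stop_validation("'nu' must be a finite numeric 2-vector (cycles/pixel)")
  if (any(abs(nu) > 0.5) || sqrt(sum(nu^2)) > 0.5)
    stop_validation("carrier frequency exceeds the Nyquist limit |nu| <= 0.5")
  if (sqrt(sum(nu^2)) <= 0)
    stop_validation("carrier frequency must be nonzero")
  if (!is_scalar_number(m) || m <= 0 || m > 1)
    stop_validation("modulation depth 'm' must lie in (0, 1]")
  if (!is_scalar_number(phi))
    stop_validation("'phi' must be a finite number (radians)")
  phi <- phi %% (2 * pi)
  structure(list(nu = as.numeric(nu), m = m, phi = phi),
            class = "carrier_code")
}

#' @export
print.carrier_code <- function(x, ...) {
  cat(sprintf("<carrier> nu = (%.5g, %.5g) cyc/px (|nu| = %.5g), m = %.3g, phi = %.3g\n",
              x$nu[1], x$nu[2], sqrt(sum(x$nu^2)), x$m, x$phi))
  invisible(x)
}

# Conjugate-aware separation between two carriers: the closest approach over
# the four pairings of {+nu_i, -nu_i} with {+nu_j, -nu_j}. Because the input
# images are real, every carrier owns a mirrored sideband at -nu; packing
# must keep filter disks around all four points disjoint.
carrier_separation <- function(nu_i, nu_j) {
  d1 <- sqrt(sum((nu_i - nu_j)^2))
  d2 <- sqrt(sum((nu_i + nu_j)^2))
  min(d1, d2)
}

#' Validated set of carriers plus decode filter geometry
#'
#' A codebook is the ordered list of `N` carrier codes used for one
#' multiplexed exposure, together with the reciprocal-space band-pass radius
#' `filter_radius` used at decode and the assumed half-width
#' `baseband_radius` of the unmodulated (DC) image content. Validation
#' enforces the packing invariants: every conjugate-aware pair separation is
#' at least `2 * filter_radius` (disjoint filter disks), every carrier
#' clears the baseband (`|nu| >= baseband_radius + filter_radius`), and
#' every filter disk stays inside Nyquist (`|nu| + filter_radius <= 0.5`).
#'
#' @param codes list of [carrier_code()] objects (ordered; order = temporal
#'   order of the frames).
#' @param filter_radius band-pass filter radius in cycles/pixel (> 0).
#' @param baseband_radius assumed baseband half-width in cycles/pixel
#'   (>= 0); defaults to `2 * filter_radius`.
#' @return An object of class `codebook`.
#' @examples
#' cb <- codebook(list(carrier_code(c(0.2, 0)), carrier_code(c(0, 0.2))),
#'                filter_radius = 0.05)
#' cb
#' @export
codebook <- function(codes, filter_radius, baseband_radius = 2 * filter_radius) {
  if (!is.list(codes) || length(codes) < 1L)
    stop_validation("'codes' must be a non-empty list of carrier codes")
  if (!all(vapply(codes, inherits, logical(1), "carrier_code")))
    stop_validation("every element of 'codes' must be a carrier_code")
  if (!is_scalar_number(filter_radius) || filter_radius <= 0)
    stop_validation("'filter_radius' must be a positive number (cycles/pixel)")
  if (!is_scalar_number(baseband_radius) || baseband_radius < 0)
    stop_validation("'baseband_radius' must be nonnegative (cycles/pixel)")
  n <- length(codes)
  r <- filter_radius
  for (i in seq_len(n)) {
    nu <- codes[[i]]$nu
    mag <- sqrt(sum(nu^2))
    if (mag + 1e-12 < baseband_radius + r)
      stop_validation(sprintf(
        "carrier %d (|nu| = %.5g) overlaps the baseband: need |nu| >= r0 + r = %.5g",
        i, mag, baseband_radius + r))
    if (mag + r > 0.5 + 1e-12)
      stop_validation(sprintf(
        "carrier %d filter disk exceeds Nyquist: |nu| + r = %.5g > 0.5", i, mag + r))
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        sep <- carrier_separation(codes[[i]]$nu, codes[[j]]$nu)
        if (sep == 0)
          stop_validation(sprintf(
            "carriers %d and %d are duplicates (or exact conjugates)", i, j))
        if (sep < 2 * r - 1e-12)
          stop_validation(sprintf(
            "carriers %d and %d are too close: conjugate-aware separation %.5g < 2r = %.5g",
            i, j, sep, 2 * r))
      }
    }
  }
  structure(list(codes = codes, filter_radius = r,
                 baseband_radius = baseband_radius),
            class = "codebook")
}

#' @export
length.codebook <- function(x) length(x$codes)

#' @export
print.codebook <- function(x, ...) {
  cat(sprintf("<codebook> %d carriers, filter radius r = %.4g, baseband r0 = %.4g (cyc/px)\n",
              length(x$codes), x$filter_radius, x$baseband_radius))
  for (i in seq_along(x$codes)) {
    cc <- x$codes[[i]]
    cat(sprintf("  [%d] nu = (%+.5f, %+.5f)  |nu| = %.5f  m = %.3g  phi = %.3g\n",
                i, cc$nu[1], cc$nu[2], sqrt(sum(cc$nu^2)), cc$m, cc$phi))
  }
  invisible(x)
}

# Internal: carriers as an n x 2 matrix.
codebook_nu <- function(cb) {
  t(vapply(cb$codes, function(cc) cc$nu, numeric(2)))
}
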