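#' Reciprocal-space packing specification
#'
#' Describes the geometry available for carrier placement: the optical
#' resolution limit (`otf_cutoff`, the outer circle of usable reciprocal
#' space), the decode filter radius `filter_radius`, the baseband half-width
#' `baseband_radius`, and the minimum conjugate-aware separation between
#' carriers. Carriers live in the annulus between
#' `baseband_radius + filter_radius` and `otf_cutoff - filter_radius`.
#'
#' `min_separation` defaults to `2 * filter_radius` (tangent filter disks);
#' the construction additionally applies a guard factor (default 1.1) to
#' leave room for the finite skirts of practical windows.
#'
#' @param n_frames number of carriers wanted (>= 1).
#' @param filter_radius decode filter radius, cycles/pixel.
#' @param baseband_radius baseband half-width, cycles/pixel; defaults to
#'   `2 * filter_radius`.
#' @param otf_cutoff optical cutoff, cycles/pixel, at most the Nyquist 0.5.
#' @param min_separation minimum conjugate-aware carrier separation,
#'   cycles/pixel.
#' @param guard_factor multiplier applied to `min_separation` by the
#'   construction (>= 1).
#' @return An object of class `packing_spec`.
#' @export
packing_spec <- function(n_frames, filter_radius,
                         baseband_radius = 2 * filter_radius,
                         otf_cutoff = 0.5,
                         min_separation = 2 * filter_radius,
                         guard_factor = 1.1) {
  if (!is_scalar_number(n_frames) || n_frames < 1)
    stop_validation("'n_frames' must be >= 1")
  if (!is_scalar_number(filter_radius) || filter_radius <= 0)
    stop_validation("'filter_radius' must be positive")
  if (!is_scalar_number(baseband_radius) || baseband_radius < 0)
    stop_validation("'baseband_radius' must be nonnegative")
  if (!is_scalar_number(otf_cutoff) || otf_cutoff <= 0 || otf_cutoff > 0.5)
    stop_validation("'otf_cutoff' must lie in (0, 0.5]")
  if (baseband_radius + 2 * filter_radius > otf_cutoff)
    stop_validation("infeasible geometry: r0 + 2r = ",
                    baseband_radius + 2 * filter_radius, " exceeds otf_cutoff = ",
                    otf_cutoff)
  if (!is_scalar_number(min_separation) || min_separation < 2 * filter_radius)
    stop_validation("'min_separation' must be >= 2 * filter_radius")
  if (!is_scalar_number(guard_factor) || guard_factor < 1)
    stop_validation("'guard_factor' must be >= 1")
  structure(list(n_frames = as.integer(n_frames),
                 filter_radius = filter_radius,
                 baseband_radius = baseband_radius,
                 otf_cutoff = otf_cutoff,
                 min_separation = min_separation,
                 guard_factor = guard_factor,
                 nyquist = 0.5),
            class = "packing_spec")
}

# Ring layout for K rings: radii and the per-ring carrier capacity under the
# effective separation sep. A single ring sits at the annulus midpoint.
ring_layout <- function(spec, k) {
  rin <- spec$baseband_radius + spec$filter_radius
  rout <- spec$otf_cutoff - spec$filter_radius
  radii <- if (k == 1) (rin + rout) / 2 else seq(rin, rout, length.out = k)
  sep <- spec$guard_factor * spec$min_separation
  caps <- vapply(radii, function(rho) {
    if (sep >= 2 * rho) 1L
    else as.integer(floor(pi / (2 * asin(sep / (2 * rho)))))
  }, integer(1))
  list(radii = radii, caps = pmax(caps, 1L), sep = sep)
}

max_rings <- function(spec) {
  rin <- spec$baseband_radius + spec$filter_radius
  rout <- spec$otf_cutoff - spec$filter_radius
  sep <- spec$guard_factor * spec$min_separation
  if (rout < rin - 1e-15) return(0L)
  1L + as.integer(floor((rout - rin) / sep + 1e-12))
}

#' Carrier capacity of the ring-packing construction
#'
#' Maximum number of carriers the deterministic concentric-ring construction
#' can place for a given packing spec. This lower-bounds the true geometric
#' packing optimum. Carriers on the same ring are spaced uniformly over
#' `[0, pi)` — conjugate symmetry of real images halves the usable angle
#' range — and rings are spaced at least one separation apart radially.
#'
#' @param spec a [packing_spec()].
#' @return Integer carrier count (0 when the annulus is empty).
#' @examples
#' packing_capacity(packing_spec(1, filter_radius = 0.02,
#'                               baseband_radius = 0.05, otf_cutoff = 0.45))
#' @export
packing_capacity <- function(spec) {
  if (!inherits(spec, "packing_spec")) stop_validation("'spec' must be a packing_spec")
  k <- max_rings(spec)
  if (k == 0L) return(0L)
  sum(ring_layout(spec, k)$caps)
}

#' Plan a codebook by concentric-ring carrier packing
#'
#' Places `n_frames` carriers deterministically in the usable annulus of
#' reciprocal space, maximally dispersed so that large decode filters can be
#' used: the smallest number of concentric rings whose capacity covers the
#' request is selected, rings are filled from the outermost (largest
#' capacity, best-resolved) inward, and within each ring angles are spaced
#' uniformly over `[0, pi)` with a small deterministic stagger between
#' rings. The returned codebook always passes its own validation, with
#' conjugate-aware separations of at least
#' `guard_factor * min_separation >= 2 * filter_radius`.
#'
#' @param spec a [packing_spec()].
#' @param m modulation depth assigned to every carrier.
#' @return A [codebook()].
#' @examples
#' plan_codebook(packing_spec(4, filter_radius = 0.03))
#' @export
plan_codebook <- function(spec, m = 1) {
  if (!inherits(spec, "packing_spec")) stop_validation("'spec' must be a packing_spec")
  kmax <- max_rings(spec)
  if (kmax == 0L)
    stop_infeasible("infeasible packing: empty annulus, otf_cutoff - r < r0 + r")
  total <- packing_capacity(spec)
  if (total < spec$n_frames)
    stop_infeasible("infeasible packing: ring construction capacity ", total,
                    " < requested n_frames ", spec$n_frames,
                    " (binding constraint: annulus [",
                    signif(spec$baseband_radius + spec$filter_radius, 4), ", ",
                    signif(spec$otf_cutoff - spec$filter_radius, 4),
                    "] with separation ",
                    signif(spec$guard_factor * spec$min_separation, 4), ")")
  k <- 1L
  while (sum(ring_layout(spec, k)$caps) < spec$n_frames) k <- k + 1L
  lay <- ring_layout(spec, k)
  # fill outermost rings first: larger circumference, finest detail retained
  ord <- order(lay$radii, decreasing = TRUE)
  remaining <- spec$n_frames
  codes <- list()
  for (ri in ord) {
    if (remaining == 0L) break
    n_here <- min(lay$caps[ri], remaining)
    stagger <- (which(ord == ri) - 1) * pi / (2 * k * max(n_here, 1))
    ang <- (seq_len(n_here) - 1) * pi / n_here + stagger
    for (a in ang) {
      codes[[length(codes) + 1L]] <-
        carrier_code(lay$radii[ri] * c(cos(a), sin(a)), m = m)
    }
    remaining <- remaining - n_here
  }
  codebook(codes, filter_radius = spec$filter_radius,
           baseband_radius = spec$baseband_radius)
}

#' Per-frame dynamic range of a shared sensor
#'
#' `N` spatially overlapping frames multiplexed onto one `B`-bit sensor
#' share its full-well capacity, so each frame keeps `B - log2(N)` bits of
#' intensity resolution (e.g., 8 overlapping frames on a 16-bit sensor keep
#' 13 bits each).
#'
#' @param bits sensor ADC bit depth (>= 1).
#' @param n_frames number of overlapping frames (>= 1).
#' @return Effective per-frame bit depth (real number).
#' @examples
#' effective_bit_depth(16, 8)  # 13
#' @export
effective_bit_depth <- function(bits, n_frames) {
  if (!is_scalar_number(bits) || bits < 1)
    stop_validation("'bits' must be >= 1")
  if (!is_scalar_number(n_frames) || n_frames < 1)
    stop_validation("'n_frames' must be >= 1")
  if (n_frames > 2^bits)
    stop_validation("n_frames = ", n_frames, " exceeds the ", 2^bits,
                    " levels of a ", bits, "-bit sensor")
  bits - log2(n_frames)
}

#' Convert cycles/pixel to line pairs per mm
#'
#' Physical spatial frequency corresponding to a detector-plane frequency:
#' `lp/mm = (cycles/pixel) / (mm/pixel)`.
#'
#' @param nu_mag spatial frequency magnitude in cycles/pixel.
#' @param pixel_pitch pixel pitch in mm/pixel (> 0).
#' @return Spatial frequency in lp/mm.
#' @examples
#' lp_per_mm(0.5, 7 / 1002)   # Nyquist of a 1002-px, 7-mm field of view
#' @export
lp_per_mm <- function(nu_mag, pixel_pitch) {
  if (!is.numeric(nu_mag) || any(!is.finite(nu_mag)) || any(nu_mag < 0))
    stop_validation("'nu_mag' must be nonnegative (cycles/pixel)")
  if (!is_scalar_number(pixel_pitch) || pixel_pitch <= 0)
    stop_validation("'pixel_pitch' must be positive (mm/pixel)")
  nu_mag / pixel_pitch
}

#' @export
print.packing_spec <- function(x, ...) {
  cat(sprintf(paste0("<packing spec> n = %d, r = %.4g, r0 = %.4g, ",
                     "otf = %.4g, sep >= %.4g (guard %.3g)\n"),
              x$n_frames, x$filter_radius, x$baseband_radius, x$otf_cutoff,
              x$min_separation, x$guard_factor))
  cat(sprintf("  ring-construction capacity: %d carriers\n",
              packing_capacity(x)))
  invisible(x)
}
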