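# Pump-probe Kerr-gate forward model. Units throughout: lengths in mm,
# times in fs, spatial frequencies in cycles/pixel.

C_MM_PER_FS <- 2.99792458e-4  # vacuum speed of light

#' Phase speed of light in a medium
#'
#' @param n_refr refractive index (>= 1).
#' @return Speed in mm/fs (`c/n`).
#' @examples
#' speed_in_medium(1.63) * 125 * 1000  # ~23 um travelled in 125 fs in CS2
#' @export
speed_in_medium <- function(n_refr = 1) {
  if (!is_scalar_number(n_refr) || n_refr < 1)
    stop_validation("'n_refr' must be >= 1")
  C_MM_PER_FS / n_refr
}

#' Frame rate implied by a read-pulse spacing
#'
#' The pulse-to-pulse separation of the read pulses is the temporal
#' resolution; its reciprocal is the frame rate. Back-to-back pulses
#' (spacing = pulse duration) give the maximum rate.
#'
#' @param spacing_fs read-pulse separation in fs (> 0).
#' @return Frame rate in THz.
#' @examples
#' frame_rate_thz(200)  # 5 THz
#' frame_rate_thz(125)  # 8 THz: back-to-back 125 fs pulses
#' @export
frame_rate_thz <- function(spacing_fs) {
  if (any(!is.finite(spacing_fs)) || any(spacing_fs <= 0))
    stop_validation("'spacing_fs' must be positive")
  1000 / spacing_fs
}

#' Gaussian laser pulse specification
#'
#' @param duration_fwhm intensity FWHM in fs (> 0).
#' @param t0 arrival time at the volume entry face, fs.
#' @param direction propagation direction (3-vector, normalised internally).
#' @param speed propagation speed in mm/fs, at most c; defaults to c.
#' @param waist transverse 1/e^2 intensity radius at the entry, mm.
#' @param divergence_angle half-angle of linear transverse growth, rad
#'   (0 = collimated; divergence is applied along the first transverse
#'   axis, the y axis for an x-propagating beam).
#' @param wavelength nm (metadata only; the model is intensity-based).
#' @param energy pulse energy in arbitrary units; scales the intensity.
#' @return An object of class `pulse_spec`.
#' @export
pulse_spec <- function(duration_fwhm, t0 = 0, direction = c(1, 0, 0),
                       speed = C_MM_PER_FS, waist = 0.25,
                       divergence_angle = 0, wavelength = 800, energy = 1) {
  if (!is_scalar_number(duration_fwhm) || duration_fwhm <= 0)
    stop_validation("'duration_fwhm' must be positive (fs)")
  if (!is_scalar_number(t0)) stop_validation("'t0' must be finite (fs)")
  if (!is.numeric(direction) || length(direction) != 3L ||
      sqrt(sum(direction^2)) == 0)
    stop_validation("'direction' must be a nonzero 3-vector")
  direction <- direction / sqrt(sum(direction^2))
  if (!is_scalar_number(speed) || speed <= 0 || speed > C_MM_PER_FS + 1e-18)
    stop_validation("'speed' must lie in (0, c], c = ", C_MM_PER_FS, " mm/fs")
  if (!is_scalar_number(waist) || waist <= 0)
    stop_validation("'waist' must be positive (mm)")
  if (!is_scalar_number(divergence_angle) || divergence_angle < 0 ||
      divergence_angle >= pi / 2)
    stop_validation("'divergence_angle' must lie in [0, pi/2) rad")
  if (!is_scalar_number(energy) || energy < 0)
    stop_validation("'energy' must be nonnegative")
  structure(list(duration_fwhm = duration_fwhm, t0 = t0,
                 direction = direction, speed = speed, waist = waist,
                 divergence_angle = divergence_angle,
                 wavelength = wavelength, energy = energy),
            class = "pulse_spec")
}

#' Kerr-sensitive medium specification
#'
#' @param n_refr refractive index (>= 1). The default 1.63 reproduces
#'   ~23 um of travel in 125 fs in CS2.
#' @param tau_relax orientational relaxation time of the induced
#'   birefringence, fs (>= 0; 0 = instantaneous gate). Default 1600 fs, a
#'   typical CS2 orientational value.
#' @param extent medium size as a 3-vector (mm).
#' @return An object of class `kerr_medium`.
#' @export
kerr_medium <- function(n_refr = 1.63, tau_relax = 1600,
                        extent = c(7, 7, 1.4)) {
  if (!is_scalar_number(n_refr) || n_refr < 1)
    stop_validation("'n_refr' must be >= 1")
  if (!is_scalar_number(tau_relax) || tau_relax < 0)
    stop_validation("'tau_relax' must be nonnegative (fs)")
  if (!is.numeric(extent) || length(extent) != 3L || any(extent <= 0))
    stop_validation("'extent' must be a positive 3-vector (mm)")
  structure(list(n_refr = n_refr, tau_relax = tau_relax,
                 extent = as.numeric(extent)),
            class = "kerr_medium")
}

#' Voxel grid and detector mapping
#'
#' The probed volume is sampled on `shape = (nx, ny, nz)` voxels of size
#' `voxel` mm; the synthetic camera observes the projection of the gated
#' signal along z onto the (x, y) plane, so a decoded frame has `ny` rows
#' and `nx` columns.
#'
#' @param shape integer 3-vector `(nx, ny, nz)`, all >= 4.
#' @param voxel voxel edge lengths `(vx, vy, vz)` in mm, all > 0.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(shape, voxel) {
  if (length(shape) != 3L || any(shape < 4))
    stop_validation("'shape' must be a 3-vector with all dims >= 4")
  if (length(voxel) != 3L || any(voxel <= 0))
    stop_validation("'voxel' must be a positive 3-vector (mm)")
  structure(list(shape = as.integer(shape), voxel = as.numeric(voxel)),
            class = "grid_spec")
}

# Geometry of a pulse relative to the medium: entry-face centre p0 and an
# orthonormal transverse basis (e1 toward global y where possible, e2
# completing the right-handed triad). Divergence acts along e1.
pulse_geometry <- function(pulse, medium) {
  d <- pulse$direction
  chord <- sum(abs(d) * medium$extent)   # exact for axis-aligned directions
  p0 <- medium$extent / 2 - d * chord / 2
  ref <- c(0, 1, 0)
  if (abs(sum(ref * d)) > 0.99) ref <- c(1, 0, 0)
  e1 <- ref - sum(ref * d) * d
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2],
          d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  list(p0 = p0, e1 = e1, e2 = e2)
}

# Decompose points (n x 3) into longitudinal coordinate xi (from the entry
# face), transverse amplitude factor, beam widths. Returns per-point lists.
pump_transverse <- function(pump, geom, pts) {
  rel <- sweep(pts, 2, geom$p0)
  xi <- drop(rel %*% pump$direction)
  t1 <- drop(rel %*% geom$e1)
  t2 <- drop(rel %*% geom$e2)
  w1 <- pump$waist + tan(pump$divergence_angle) * pmax(xi, 0)
  amp <- pump$energy * (pump$waist / w1) *
    exp(-2 * (t1^2 / w1^2 + t2^2 / pump$waist^2))
  list(xi = xi, amp = amp)
}

#' Pump pulse intensity at a point and time
#'
#' Separable Gaussian pulse: a longitudinal envelope
#' `exp(-4 ln2 ((xi - v (t - t0)) / (v * fwhm))^2)` along the propagation
#' direction (with `xi` measured from the entry face of the medium) times a
#' transverse Gaussian whose 1/e^2 radius grows linearly with the
#' divergence angle along the first transverse axis. For a collimated beam
#' the pulse translates rigidly at its phase speed.
#'
#' @param pump a [pulse_spec()].
#' @param medium a [kerr_medium()] (fixes the entry geometry).
#' @param point 3-vector in mm, or an `n x 3` matrix of points.
#' @param t time in fs (scalar, or vector matching the points).
#' @return Intensity (same units as `energy`), vectorised over points.
#' @export
pump_intensity <- function(pump, medium, point, t) {
  if (!inherits(pump, "pulse_spec")) stop_validation("'pump' must be a pulse_spec")
  if (!inherits(medium, "kerr_medium")) stop_validation("'medium' must be a kerr_medium")
  pts <- if (is.matrix(point)) point else matrix(point, ncol = 3)
  geom <- pulse_geometry(pump, medium)
  tr <- pump_transverse(pump, geom, pts)
  v <- pump$speed
  arg <- (tr$xi - v * (t - pump$t0)) / (v * pump$duration_fwhm)
  drop(tr$amp * exp(-4 * log(2) * arg^2))
}

# Exponentially modified Gaussian gate kernel: response at time offset
# delta = t - tc of a unit-peak temporal Gaussian (sd sigma) convolved with
# exp(-u/tau)/tau. Stable for all tau > 0 via erfcx; tau = 0 handled by the
# caller (delta-kernel limit = the Gaussian itself).
emg_gate <- function(delta, sigma, tau) {
  x <- sigma / (sqrt(2) * tau) - delta / (sqrt(2) * sigma)
  out <- numeric(length(delta))
  hi <- x > -5
  if (any(hi))
    out[hi] <- (sigma / tau) * sqrt(pi / 2) * erfcx_stable(x[hi]) *
      exp(-delta[hi]^2 / (2 * sigma^2))
  if (any(!hi))  # deep tail: erfc(x) ~ 2, pure exponential decay
    out[!hi] <- (sigma / tau) * sqrt(2 * pi) *
      exp(sigma^2 / (2 * tau^2) - delta[!hi] / tau)
  dim(out) <- dim(delta)
  out
}

#' Kerr gate strength at a point and time
#'
#' The gate is the pump-induced birefringence, modelled as the pump
#' intensity convolved with an exponential orientational-relaxation kernel:
#' `G(p, t) = (1/tau) * integral_{-inf}^{t} I_pump(p, t') exp(-(t - t')/tau) dt'`.
#' For `tau_relax = 0` the kernel collapses to a delta function and
#' `G = I_pump`. Because the pump is temporally Gaussian at any fixed
#' point, the convolution has an exact exponentially-modified-Gaussian
#' closed form, which is what this function evaluates (numerically
#' stabilised for small `tau`).
#'
#' @inheritParams pump_intensity
#' @return Gate strength, vectorised over points.
#' @export
gate_response <- function(pump, medium, point, t) {
  if (!inherits(pump, "pulse_spec")) stop_validation("'pump' must be a pulse_spec")
  if (!inherits(medium, "kerr_medium")) stop_validation("'medium' must be a kerr_medium")
  tau <- medium$tau_relax
  if (tau == 0) return(pump_intensity(pump, medium, point, t))
  pts <- if (is.matrix(point)) point else matrix(point, ncol = 3)
  geom <- pulse_geometry(pump, medium)
  tr <- pump_transverse(pump, geom, pts)
  sigma <- pump$duration_fwhm / (2 * sqrt(2 * log(2)))
  tc <- pump$t0 + tr$xi / pump$speed
  drop(tr$amp * emg_gate(t - tc, sigma, tau))
}

#' Gated image of one read pulse
#'
#' The signal a camera records for one read pulse: the read pulse
#' (propagating along +z at `c/n`, temporally Gaussian, spatially uniform
#' over the (x, y) aperture) samples the Kerr gate as it traverses the
#' medium, and the camera integrates the transmitted light along z and
#' over time:
#' `S(x, y) = integral dz integral dt I_read(z, t) * G(x, y, z, t)`,
#' evaluated by midpoint quadrature on the voxel grid and a time grid with
#' step `min(read, pump duration)/10`. The pump must propagate along +x
#' and the read along +z (the projection geometry of the detector).
#'
#' @param pump pump [pulse_spec()], direction `(1, 0, 0)`.
#' @param read read [pulse_spec()], direction `(0, 0, 1)`; its `t0` is the
#'   read delay (arrival at the z = 0 face).
#' @param medium a [kerr_medium()]; its extent must match the grid extent.
#' @param grid a [grid_spec()]; the z voxel must give at least 4 samples
#'   across the read pulse length, else the quadrature is refused.
#' @param time_oversample multiply the default time resolution by this
#'   integer factor (>= 1), e.g. for convergence checks.
#' @return A [frame()] of `ny` rows by `nx` columns with
#'   `pixel_pitch = vx` and `time_tag` equal to the time the read pulse
#'   crosses the medium centre.
#' @export
frame_signal <- function(pump, read, medium, grid, time_oversample = 1) {
  if (!inherits(pump, "pulse_spec") || !inherits(read, "pulse_spec"))
    stop_validation("'pump' and 'read' must be pulse_spec objects")
  if (!inherits(medium, "kerr_medium")) stop_validation("'medium' must be a kerr_medium")
  if (!inherits(grid, "grid_spec")) stop_validation("'grid' must be a grid_spec")
  if (abs(sum(pump$direction * read$direction)) > 1e-9)
    stop_validation("pump and read directions must be orthogonal")
  if (max(abs(pump$direction - c(1, 0, 0))) > 1e-9 ||
      max(abs(read$direction - c(0, 0, 1))) > 1e-9)
    stop_validation("supported geometry: pump along +x, read along +z")
  ext <- grid$shape * grid$voxel
  if (max(abs(ext - medium$extent)) > 1e-9)
    stop_validation("grid extent (", paste(signif(ext, 6), collapse = ", "),
                    ") must equal the medium extent")
  nx <- grid$shape[1]; ny <- grid$shape[2]; nz <- grid$shape[3]
  vx <- grid$voxel[1]; vy <- grid$voxel[2]; vz <- grid$voxel[3]
  vr <- read$speed
  read_len <- vr * read$duration_fwhm
  if (vz > read_len / 4)
    stop_validation("z grid too coarse: fewer than 4 voxels across the read ",
                    "pulse length (need vz <= ", signif(read_len / 4, 4), " mm)")
  if (!is_scalar_number(time_oversample) || time_oversample < 1)
    stop_validation("'time_oversample' must be >= 1")
  dt <- min(read$duration_fwhm, pump$duration_fwhm) / (10 * time_oversample)
  t_lo <- read$t0 - 4 * read$duration_fwhm
  t_hi <- read$t0 + ext[3] / vr + 4 * read$duration_fwhm
  nt <- ceiling((t_hi - t_lo) / dt)
  ts <- t_lo + (seq_len(nt) - 0.5) * dt
  xs <- (seq_len(nx) - 0.5) * vx
  ys <- (seq_len(ny) - 0.5) * vy
  zs <- (seq_len(nz) - 0.5) * vz
  yc <- ext[2] / 2; zc <- ext[3] / 2

  # read envelope, nt x nz
  ir <- read$energy *
    exp(-4 * log(2) * (outer(-vr * (ts - read$t0), zs, "+") / read_len)^2)
  # temporal gate response per x column, nt x nx
  sigma <- pump$duration_fwhm / (2 * sqrt(2 * log(2)))
  tc <- pump$t0 + xs / pump$speed
  delta <- outer(ts, tc, "-")
  g <- if (medium$tau_relax == 0) exp(-delta^2 / (2 * sigma^2))
       else emg_gate(delta, sigma, medium$tau_relax)
  m1 <- crossprod(ir, g) * dt            # nz x nx: time-integrated overlap
  ez <- exp(-2 * (zs - zc)^2 / pump$waist^2)
  s1 <- drop(ez %*% m1) * vz             # nx: z-projected gated signal
  w1 <- pump$waist + tan(pump$divergence_angle) * pmax(xs, 0)
  amp <- pump$energy * (pump$waist / w1)
  ey <- exp(outer(-2 * (ys - yc)^2, 1 / w1^2))   # ny x nx
  s <- sweep(ey, 2, amp * s1, "*")
  frame(s, pixel_pitch = vx, time_tag = read$t0 + zc / vr)
}

#' Simulate a read-pulse train into a frame sequence
#'
#' Runs [frame_signal()] once per read delay. With `tau_relax = 0` and a
#' collimated pump, successive frames are rigid translates whose centroid
#' advances at the pump speed.
#'
#' @param pump pump [pulse_spec()].
#' @param read_delays strictly increasing read arrival times, fs (>= 2).
#' @param medium a [kerr_medium()].
#' @param grid a [grid_spec()].
#' @param read template read [pulse_spec()] whose `t0` is replaced by each
#'   delay; defaults to a pulse matching the pump duration and speed,
#'   propagating along +z.
#' @return A [frame_sequence()] with `times = read_delays`.
#' @export
simulate_sequence <- function(pump, read_delays, medium, grid, read = NULL) {
  if (length(read_delays) < 2L)
    stop_validation("'read_delays' must contain at least 2 delays")
  if (any(diff(read_delays) <= 0))
    stop_validation("'read_delays' must be strictly increasing")
  if (is.null(read))
    read <- pulse_spec(duration_fwhm = pump$duration_fwhm,
                       direction = c(0, 0, 1), speed = pump$speed,
                       waist = pump$waist)
  frames <- lapply(read_delays, function(d) {
    read$t0 <- d
    frame_signal(pump, read, medium, grid)
  })
  frame_sequence(frames, as.numeric(read_delays))
}

#' Sum a frame along one axis
#'
#' Collapses a frame to a 1D intensity profile, e.g. the vertical summation
#' used to track a streak as it advances across the detector.
#'
#' @param frm a [frame()] (or matrix).
#' @param axis axis that is summed over: `"rows"` (default; returns one
#'   value per column, length `W`) or `"columns"` (one value per row,
#'   length `H`).
#' @return Numeric vector profile.
#' @export
axial_profile <- function(frm, axis = c("rows", "columns")) {
  axis <- match.arg(axis)
  px <- pixel_matrix(frm)
  if (axis == "rows") colSums(px) else rowSums(px)
}
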