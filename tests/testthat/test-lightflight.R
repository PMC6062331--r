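# Pump-probe Kerr-gate forward model.

test_that("pump pulse keeps unit peak and translates rigidly", {
  v <- speed_in_medium(1.63)
  pump <- pulse_spec(125, t0 = 0, direction = c(1, 0, 0), speed = v,
                     waist = 0.3)
  med <- kerr_medium(1.63, tau_relax = 0, extent = c(7, 7, 1.4))
  # on-axis pulse centre: intensity equals the peak at any time
  for (t in c(500, 5000, 20000)) {
    pt <- c(v * t, 3.5, 0.7)
    expect_equal(pump_intensity(pump, med, pt, t), 1, tolerance = 1e-12)
  }
  # centroid along x advances by exactly speed * dt
  xs <- seq(1, 6, by = 2e-4)
  pts <- cbind(xs, 3.5, 0.7)
  cen <- function(t) {
    i <- pump_intensity(pump, med, pts, t)
    sum(i * xs) / sum(i)
  }
  t1 <- 3.2 / v
  adv <- cen(t1 + 125) - cen(t1)
  expect_equal(adv, v * 125, tolerance = 1e-9)
  expect_equal(round(adv, 3), 0.023)      # ~23 um in 125 fs in CS2
})

test_that("gate response has the right limits and closed form", {
  v <- speed_in_medium(1.63)
  pump <- pulse_spec(125, t0 = 0, direction = c(1, 0, 0), speed = v,
                     waist = 0.25)
  pt <- c(2.0, 3.5, 0.7)
  tpk <- 2.0 / v                          # pump centre crosses the point

  # tau -> 0: delta-kernel limit recovers the instantaneous intensity
  med0 <- kerr_medium(1.63, tau_relax = 1e-3, extent = c(7, 7, 1.4))
  medd <- kerr_medium(1.63, tau_relax = 0, extent = c(7, 7, 1.4))
  g <- gate_response(pump, med0, pt, tpk)
  i <- pump_intensity(pump, medd, pt, tpk)
  expect_equal(g, i, tolerance = 1e-6)
  expect_identical(gate_response(pump, medd, pt, tpk), i)  # tau = 0 exactly

  # finite tau: matches brute-force quadrature of the convolution integral
  tau <- 1600
  med <- kerr_medium(1.63, tau_relax = tau, extent = c(7, 7, 1.4))
  for (t in tpk + c(-150, 0, 400, 2500)) {
    g <- gate_response(pump, med, pt, t)
    o <- stats::integrate(function(u)
      pump_intensity(pump, med, matrix(pt, 1), t - u) * exp(-u / tau) / tau,
      0, 20 * tau, rel.tol = 1e-12, abs.tol = 0, subdivisions = 500L)$value
    expect_equal(g, o, tolerance = 1e-8)
  }

  # long after passage: pure exponential decay at rate 1/tau
  ts <- tpk + seq(4000, 9000, by = 1000)
  lg <- log(gate_response(pump, med, matrix(rep(pt, length(ts)), ncol = 3,
                                            byrow = TRUE), ts))
  slopes <- diff(lg) / diff(ts)
  expect_equal(slopes, rep(-1 / tau, length(slopes)), tolerance = 1e-6)
})

test_that("frame_signal vanishes without overlap and is linear in read energy", {
  sc <- lif_scene(nx = 64, ny = 16, nz = 256)
  # read finishes its sweep ~25 ps before the pump reaches the cell
  early <- sc$read; early$t0 <- -30000
  f0 <- frame_signal(sc$pump, early, sc$medium, sc$grid)
  ontime <- sc$read; ontime$t0 <- sc$delay_for_x(3.5)
  f1 <- frame_signal(sc$pump, ontime, sc$medium, sc$grid)
  expect_lt(max(f0$pixels), 1e-12 * max(f1$pixels))

  double <- ontime; double$energy <- 2
  f2 <- frame_signal(sc$pump, double, sc$medium, sc$grid)
  expect_equal(f2$pixels, 2 * f1$pixels, tolerance = 1e-12)
})

test_that("streaks advance ~3 detector pixels per 125 fs (CS2, 7 mm / 1002 px)", {
  sc <- lif_scene()                        # 1002-px, 7-mm grid, tau = 0
  r1 <- sc$read; r1$t0 <- sc$delay_for_x(3.0)
  r2 <- sc$read; r2$t0 <- r1$t0 + 125
  f1 <- frame_signal(sc$pump, r1, sc$medium, sc$grid)
  f2 <- frame_signal(sc$pump, r2, sc$medium, sc$grid)
  shift_px <- profile_centroid(axial_profile(f2)) -
    profile_centroid(axial_profile(f1))
  expect_identical(round(shift_px), 3)
  # the same number from pure arithmetic: 23 um / (7 mm / 1002 px)
  expect_identical(round(speed_in_medium(1.63) * 125 / (7 / 1002)), 3)
})

test_that("grid and geometry preconditions are enforced", {
  sc <- lif_scene(nx = 64, ny = 16, nz = 256)
  coarse <- grid_spec(c(64, 16, 16), c(7, 7, 1.4) / c(64, 16, 16))
  expect_error(frame_signal(sc$pump, sc$read, sc$medium, coarse),
               "too coarse")
  diag_read <- pulse_spec(125, direction = c(1, 0, 1), speed = sc$v)
  expect_error(frame_signal(sc$pump, diag_read, sc$medium, sc$grid),
               "orthogonal")
  wrong_ext <- kerr_medium(1.63, 0, extent = c(6, 7, 1.4))
  expect_error(frame_signal(sc$pump, sc$read, wrong_ext, sc$grid),
               "extent")
})

test_that("sequences translate rigidly and track the pump speed", {
  sc <- lif_scene(nx = 702, ny = 16, nz = 256)   # 7 mm on 702 px
  sc$grid <- grid_spec(c(702, 16, 256), c(7, 7, 1.4) / c(702, 16, 256))
  delays <- sc$delay_for_x(2.6) + (0:3) * 125
  seq4 <- simulate_sequence(sc$pump, delays, sc$medium, sc$grid, sc$read)
  expect_length(seq4, 4)
  expect_identical(seq4$times, delays)

  # centroid speed equals the pump speed to 0.1% (linear fit over 4 frames)
  px <- sc$grid$voxel[1]
  cens <- vapply(seq4$frames, function(f)
    profile_centroid(axial_profile(f)) * px, numeric(1))
  speed <- stats::coef(stats::lm(cens ~ delays))[[2]]
  expect_equal(speed, sc$v, tolerance = 1e-3)

  # successive frames are translates: cross-correlation peak at the shift
  p1 <- axial_profile(seq4$frames[[1]]); p2 <- axial_profile(seq4$frames[[2]])
  lags <- -8:8
  cc <- vapply(lags, function(l) {
    i <- seq_along(p1)
    j <- i + l
    ok <- j >= 1 & j <= length(p1)
    sum(p1[i[ok]] * p2[j[ok]])
  }, numeric(1))
  expect_identical(lags[which.max(cc)], as.integer(round(sc$v * 125 / px)))

  # profile peaks advance monotonically with delay
  peaks <- vapply(seq4$frames, function(f) which.max(axial_profile(f)),
                  integer(1))
  expect_true(all(diff(peaks) > 0))

  expect_error(simulate_sequence(sc$pump, c(0, 0, 125), sc$medium, sc$grid),
               "strictly increasing")
})

test_that("relaxation leaves a trailing skirt behind the streak", {
  sc0 <- lif_scene(nx = 256, ny = 16, nz = 256)
  g256 <- grid_spec(c(256, 16, 256), c(7, 7, 1.4) / c(256, 16, 256))
  rd <- sc0$read; rd$t0 <- sc0$delay_for_x(4.5)
  med0 <- kerr_medium(1.63, tau_relax = 0, extent = c(7, 7, 1.4))
  med1 <- kerr_medium(1.63, tau_relax = 1600, extent = c(7, 7, 1.4))
  p0 <- axial_profile(frame_signal(sc0$pump, rd, med0, g256))
  p1 <- axial_profile(frame_signal(sc0$pump, rd, med1, g256))
  ipk <- which.max(p0)
  behind <- 1:(ipk - 12)                   # clearly behind the front
  expect_true(all(p1[behind] > p0[behind]))
})

test_that("the quadrature is converged at the default resolution", {
  # the beam waist must be resolved in y so that pixel block means compare;
  # z and t are the quadrature axes being refined
  ext <- c(7, 2, 1.4)
  v <- speed_in_medium(1.63)
  pump <- pulse_spec(125, t0 = 0, direction = c(1, 0, 0), speed = v,
                     waist = 0.25)
  read <- pulse_spec(125, direction = c(0, 0, 1), speed = v)
  read$t0 <- 3.5 / v - (ext[3] / 2) / v
  med <- kerr_medium(1.63, 800, ext)
  g1 <- grid_spec(c(128, 64, 256), ext / c(128, 64, 256))
  g2 <- grid_spec(c(256, 128, 512), ext / c(256, 128, 512))
  f1 <- frame_signal(pump, read, med, g1)$pixels
  f2 <- frame_signal(pump, read, med, g2, time_oversample = 2)$pixels
  # block-average the refined frame back onto the coarse grid
  o <- seq(1, nrow(f2) - 1, 2); p <- seq(1, ncol(f2) - 1, 2)
  blk <- 0.25 * (f2[o, p] + f2[o + 1, p] + f2[o, p + 1] + f2[o + 1, p + 1])
  expect_lt(max(abs(blk - f1)) / max(f1), 0.01)
})

test_that("frame rate arithmetic matches the pulse spacing", {
  expect_identical(frame_rate_thz(200), 5)
  expect_identical(frame_rate_thz(1000), 1)
  expect_identical(frame_rate_thz(400), 2.5)
  expect_identical(frame_rate_thz(125), 8)
})

test_that("axial profiles sum intensities along one axis", {
  f <- frame(matrix(2, 16, 24))
  expect_identical(axial_profile(f, "rows"), rep(32, 24))      # H * value
  expect_identical(axial_profile(f, "columns"), rep(48, 16))
  set.seed(30)
  g <- frame(matrix(runif(16 * 24), 16, 24))
  expect_equal(sum(axial_profile(g, "rows")), sum(g$pixels), tolerance = 1e-12)
})
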