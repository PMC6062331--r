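# Decoding: spectra, carrier detection, band-pass lock-in extraction.

test_that("spectrum of simple images has the expected support", {
  # constant image: single DC bin, at both even and odd sizes
  for (d in list(c(16, 16), c(17, 24))) {
    sp <- image_spectrum(frame(matrix(3, d[1], d[2])))
    a <- Mod(sp$values)
    dc <- which(a == max(a), arr.ind = TRUE)
    expect_identical(as.integer(dc),
                     as.integer(floor(d / 2) + 1))
    expect_lt(max(a[-which.max(a)]), 1e-9 * max(a))
  }
  # commensurate pure cosine: exactly three nonzero bins (DC, +/- nu)
  g <- modulate(frame(matrix(1, 16, 32)), carrier_code(c(1 / 8, 0)))
  a <- Mod(image_spectrum(g)$values)
  expect_identical(sum(a > 1e-9 * max(a)), 3L)
})

test_that("spectrum satisfies Parseval and conjugate symmetry", {
  set.seed(5)
  for (d in list(c(16, 16), c(21, 16), c(32, 48))) {
    img <- matrix(runif(d[1] * d[2]), d[1], d[2])
    sp <- image_spectrum(img)
    # Parseval against direct summation
    expect_equal(sum(img^2), sum(Mod(sp$values)^2) / prod(d),
                 tolerance = 1e-9)
    # real image: F(-k) = conj(F(k))
    v <- framecodec:::ifftshift2(sp$values)
    flipped <- v[c(1, d[1]:2), c(1, d[2]:2)]
    expect_lt(max(Mod(v - Conj(flipped))), 1e-9 * max(Mod(v)))
  }
})

test_that("planted carriers are recovered to sub-bin accuracy", {
  set.seed(6)
  cb <- plan_codebook(packing_spec(4, filter_radius = 0.035,
                                   baseband_radius = 0.07,
                                   otf_cutoff = 0.45))
  n <- 128
  fr <- replicate(4, smooth_test_frame(n, cutoff = 0.006), simplify = FALSE)
  ex <- compose(fr, cb, sensor_model())
  nu <- detect_carriers(ex, 4, exclusion_r0 = 0.1)
  truth <- framecodec:::codebook_nu(cb)
  err <- vapply(seq_len(4), function(i) {
    min(apply(truth, 1, function(tv)
      min(sqrt(sum((tv - nu[i, ])^2)), sqrt(sum((tv + nu[i, ])^2)))))
  }, numeric(1))
  expect_lt(max(err), 1 / (2 * n))
  # recovered carriers come from the upper half-plane (centroid refinement
  # may move an on-axis peak a fraction of a bin below it)
  expect_true(all(nu[, 2] > -1 / n))
})

test_that("an unmodulated image yields a carriers-not-found error", {
  expect_error(detect_carriers(frame(matrix(1, 64, 64)), 2),
               "carriers not found")
  expect_error(detect_carriers(frame(matrix(0.3, 128, 96)), 1),
               "carriers not found")
})

test_that("all 16 carriers of a detector-scale encoding are recovered", {
  set.seed(8)
  cb <- plan_codebook(packing_spec(16, filter_radius = 0.02,
                                   baseband_radius = 0.05,
                                   otf_cutoff = 0.45))
  h <- 1002; w <- 1004
  tp_h <- framecodec:::tukey_window(h, 0.4)
  tp_w <- framecodec:::tukey_window(w, 0.4)
  base <- (tp_h %o% tp_w)
  fr <- lapply(seq_len(16), function(i) {
    ph <- outer((0:(h - 1)) / h, (0:(w - 1)) / w,
                function(a, b) sin(2 * pi * (3 * a + (i %% 5) * b)))
    frame(base * (1 + 0.3 * ph))
  })
  ex <- compose(fr, cb, sensor_model())
  nu <- detect_carriers(ex, 16, exclusion_r0 = 0.06)
  truth <- framecodec:::codebook_nu(cb)
  err <- vapply(seq_len(16), function(i) {
    min(apply(truth, 1, function(tv)
      min(sqrt(sum((tv - nu[i, ])^2)), sqrt(sum((tv + nu[i, ])^2)))))
  }, numeric(1))
  expect_lt(max(err), 1 / (2 * min(h, w)))
  # and each planted carrier is matched by exactly one detection
  assign_err <- vapply(seq_len(16), function(k) {
    min(apply(nu, 1, function(d)
      min(sqrt(sum((d - truth[k, ])^2)), sqrt(sum((d + truth[k, ])^2)))))
  }, numeric(1))
  expect_lt(max(assign_err), 1 / (2 * min(h, w)))
})

test_that("a constant frame round-trips through encode and extract", {
  cval <- 0.7
  n <- 256
  cb <- codebook(list(carrier_code(c(0.2, 0.1))), filter_radius = 0.05)
  ex <- compose(list(frame(matrix(cval, n, n))), cb, sensor_model())
  dec <- extract_frame(ex, cb$codes[[1]]$nu,
                       band_filter(cb$codes[[1]]$nu, cb$filter_radius))
  inner <- dec$pixels[6:(n - 5), 6:(n - 5)]
  expect_lt(max(abs(inner - cval)) / cval, 0.01)
})

test_that("four band-limited frames decode with NRMSE below 1 percent", {
  set.seed(9)
  cb <- plan_codebook(packing_spec(4, filter_radius = 0.035,
                                   baseband_radius = 0.07,
                                   otf_cutoff = 0.45))
  n <- 192
  fr <- replicate(4, smooth_test_frame(n), simplify = FALSE)
  ex <- compose(fr, cb, sensor_model())
  dec <- demultiplex(ex, window = "tukey", window_param = 0.3)
  for (i in seq_len(4)) {
    fid <- fidelity(dec[[i]], fr[[i]])
    expect_lt(fid$nrmse, 0.01)
    expect_gt(fid$pearson_r, 0.999)
  }
})

test_that("Fourier-path extraction equals the spatial lock-in oracle", {
  set.seed(10)
  cases <- list(
    list(nu = c(0.19, 0.11), r = 0.08, win = "gaussian", m = 0.7),
    list(nu = c(0.25, 0.00), r = 0.06, win = "tukey", m = 1),
    list(nu = c(-0.13, 0.21), r = 0.10, win = "hard", m = 0.4)
  )
  for (cs in cases) {
    img <- matrix(runif(32 * 32), 32, 32)
    filt <- band_filter(cs$nu, cs$r, window = cs$win)
    imp <- extract_frame(img, cs$nu, filt, m = cs$m, gain = 1)$pixels
    ora <- spatial_lockin_oracle(img, cs$nu, filt, cs$m)
    expect_lt(max(abs(imp - ora)) / max(ora), 1e-9)
  }
})

test_that("demultiplex preserves codebook order and propagates errors", {
  set.seed(11)
  c1 <- carrier_code(c(0.22, 0)); c2 <- carrier_code(c(0, 0.22))
  cb12 <- codebook(list(c1, c2), filter_radius = 0.05)
  cb21 <- codebook(list(c2, c1), filter_radius = 0.05)
  fr <- list(smooth_test_frame(64), smooth_test_frame(64))
  ex <- compose(fr, cb12, sensor_model())
  d12 <- demultiplex(ex, cb12)
  d21 <- demultiplex(ex, cb21)
  expect_identical(d12[[1]]$pixels, d21[[2]]$pixels)
  expect_identical(d12[[2]]$pixels, d21[[1]]$pixels)

  # single carrier: demultiplex reduces exactly to extract_frame
  cb1 <- codebook(list(c1), filter_radius = 0.05)
  ex1 <- compose(fr[1], cb1, sensor_model())
  d1 <- demultiplex(ex1, cb1)
  e1 <- extract_frame(ex1, c1$nu, band_filter(c1$nu, 0.05))
  expect_identical(d1[[1]]$pixels, e1$pixels)

  # failures carry the frame index
  cbbad <- codebook(list(carrier_code(c(0.47, 0))), filter_radius = 0.02)
  cbbad$filter_radius <- 0.2               # force Nyquist violation at decode
  expect_error(demultiplex(ex1, cbbad), "frame 1: .*Nyquist")
})

test_that("a blank input channel stays blank after decoding", {
  set.seed(12)
  cb <- plan_codebook(packing_spec(4, filter_radius = 0.035,
                                   baseband_radius = 0.07,
                                   otf_cutoff = 0.45))
  n <- 192
  fr <- c(replicate(3, smooth_test_frame(n), simplify = FALSE),
          list(frame(matrix(0, n, n))))
  ex <- compose(fr, cb, sensor_model())
  dec <- demultiplex(ex, window = "tukey", window_param = 0.3)
  rng <- max(vapply(fr[1:3], function(f) diff(range(f$pixels)), numeric(1)))
  leak <- sqrt(mean(dec[[4]]$pixels[6:(n - 5), 6:(n - 5)]^2)) / rng
  expect_lt(leak, 0.02)
})

test_that("filter radius sets the two-point resolution, monotonically", {
  two_point_resolved <- function(s, r) {
    img <- matrix(0, 64, 64)
    img[32, 32 - round(s / 2)] <- 1
    img[32, 32 + s - round(s / 2)] <- 1
    ex <- modulate(frame(img + 1e-6), carrier_code(c(0.25, 0.1)))$pixels
    dec <- extract_frame(ex, c(0.25, 0.1), band_filter(c(0.25, 0.1), r),
                         gain = 1)$pixels
    row <- dec[32, ]
    pk <- which(diff(sign(diff(row))) == -2) + 1
    length(pk[row[pk] > 0.1 * max(row)]) >= 2
  }
  seps <- c(3, 5, 8, 12, 20, 30)
  radii <- c(0.04, 0.08, 0.16)
  res <- vapply(radii, function(r) vapply(seps, two_point_resolved, logical(1),
                                          r = r), logical(length(seps)))
  # once resolved at some separation, larger separations stay resolved
  for (k in seq_along(radii)) expect_true(all(diff(res[, k]) >= 0))
  # larger filters resolve more: resolved set grows with r
  expect_true(all(res[, 1] <= res[, 2]) && all(res[, 2] <= res[, 3]))
  # the transition happens near the filter-limited scale 1/(2r)
  for (k in seq_along(radii)) {
    lim <- 1 / (2 * radii[k])
    expect_true(all(!res[seps < 0.9 * lim, k]))
    expect_true(all(res[seps > 2.2 * lim, k]))
  }
})

test_that("crosstalk grows strictly as carriers close below 2r", {
  set.seed(13)
  n <- 160
  a <- smooth_test_frame(n, cutoff = 0.006)
  r <- 0.04
  c1 <- c(0.18, 0.05)
  u <- c(0.6, 0.8)
  leak <- vapply(c(2, 1.6, 1.2, 0.9), function(k) {
    c2 <- c1 + k * r * u
    ex <- modulate(a, carrier_code(c1))$pixels
    dec <- extract_frame(ex, c2, band_filter(c2, r), gain = 1)$pixels
    sqrt(mean(dec[6:(n - 5), 6:(n - 5)]^2)) / diff(range(a$pixels))
  }, numeric(1))
  expect_true(all(diff(leak) > 0))
})

test_that("decoding commutes with global intensity scaling", {
  set.seed(14)
  img <- modulate(smooth_test_frame(64), carrier_code(c(0.2, 0.1)))$pixels
  filt <- band_filter(c(0.2, 0.1), 0.05)
  d1 <- extract_frame(img, c(0.2, 0.1), filt, gain = 1)$pixels
  d2 <- extract_frame(3.5 * img, c(0.2, 0.1), filt, gain = 1)$pixels
  expect_equal(d2, 3.5 * d1, tolerance = 1e-12)
})
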