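#' Ordered frame sequence with time stamps
#'
#' @param frames list of at least two equally-shaped [frame()] objects.
#' @param times strictly increasing times in fs, one per frame.
#' @return An object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, times) {
  if (!is.list(frames) || length(frames) < 2L)
    stop_validation("'frames' must be a list of at least 2 frames")
  frames <- lapply(frames, as_frame)
  d <- dim(frames[[1]]$pixels)
  if (!all(vapply(frames, function(f) identical(dim(f$pixels), d), logical(1))))
    stop_validation("all frames must share one shape")
  if (!is.numeric(times) || length(times) != length(frames))
    stop_validation("'times' must be numeric with one entry per frame")
  if (any(!is.finite(times)) || any(diff(times) <= 0))
    stop_validation("'times' must be finite and strictly increasing")
  structure(list(frames = frames, times = as.numeric(times)),
            class = "frame_sequence")
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]]$pixels)
  cat(sprintf("<frame sequence> %d frames of %d x %d px, t = %s fs\n",
              length(x$frames), d[1], d[2],
              paste(signif(x$times, 6), collapse = ", ")))
  invisible(x)
}

# Vectorised monotone (Fritsch-Carlson) Hermite slopes for per-pixel cubic
# interpolation: f is an npix x n matrix of pixel time-series, ts the n
# sample times. Returns npix x n slopes.
fc_slopes <- function(f, ts) {
  n <- length(ts)
  h <- diff(ts)
  d <- sweep(f[, -1, drop = FALSE] - f[, -n, drop = FALSE], 2, h, "/")
  m <- matrix(0, nrow(f), n)
  m[, 1] <- d[, 1]
  m[, n] <- d[, n - 1]
  if (n > 2) {
    for (k in 2:(n - 1)) {
      dl <- d[, k - 1]; dr <- d[, k]
      avg <- (dl + dr) / 2
      avg[dl * dr <= 0] <- 0           # local extremum: flat tangent
      m[, k] <- avg
    }
  }
  # limiter: flat tangents on flat intervals, alpha^2 + beta^2 <= 9 elsewhere
  for (k in seq_len(n - 1)) {
    dk <- d[, k]
    z <- dk == 0
    m[z, k] <- 0
    m[z, k + 1] <- 0
    if (all(z)) next
    a <- m[, k] / ifelse(z, 1, dk)
    b <- m[, k + 1] / ifelse(z, 1, dk)
    r <- sqrt(a^2 + b^2)
    shrink <- !z & r > 3
    if (any(shrink)) {
      m[shrink, k] <- 3 * a[shrink] / r[shrink] * dk[shrink]
      m[shrink, k + 1] <- 3 * b[shrink] / r[shrink] * dk[shrink]
    }
  }
  m
}

#' Interpolate a frame sequence in time
#'
#' Per-pixel interpolation along the time axis of a decoded (or simulated)
#' frame sequence, used to reconstruct wave-front states between recorded
#' frames. Queries at sample times return the stored frames bit-exactly.
#' `"linear"` mode returns convex per-pixel combinations (output bounded by
#' the neighbouring frames' per-pixel min/max); `"cubic"` uses a
#' monotonicity-limited Hermite spline per pixel. Extrapolation is refused.
#'
#' @param seq a [frame_sequence()].
#' @param query_times times in fs, all within `range(seq$times)`.
#' @param mode `"linear"` (default) or `"cubic"`.
#' @return A `frame_sequence` at the query times (must be >= 2 strictly
#'   increasing queries; use a single call per time otherwise).
#' @export
reconstruct_wavefront <- function(seq, query_times,
                                  mode = c("linear", "cubic")) {
  mode <- match.arg(mode)
  if (!inherits(seq, "frame_sequence"))
    stop_validation("'seq' must be a frame_sequence")
  ts <- seq$times
  if (any(query_times < ts[1] - 1e-12) || any(query_times > ts[length(ts)] + 1e-12))
    stop_validation("extrapolation requested: query times must lie within [",
                    ts[1], ", ", ts[length(ts)], "] fs")
  d <- dim(seq$frames[[1]]$pixels)
  pitch <- seq$frames[[1]]$pixel_pitch
  f <- vapply(seq$frames, function(fr) as.vector(fr$pixels),
              numeric(prod(d)))               # npix x n
  m <- if (mode == "cubic") fc_slopes(f, ts) else NULL
  interp_one <- function(tq) {
    k <- findInterval(tq, ts, rightmost.closed = TRUE)
    if (tq == ts[k]) return(seq$frames[[k]]$pixels)        # bit-exact
    if (k < length(ts) && tq == ts[k + 1]) return(seq$frames[[k + 1]]$pixels)
    h <- ts[k + 1] - ts[k]
    u <- (tq - ts[k]) / h
    v <- if (mode == "linear") {
      (1 - u) * f[, k] + u * f[, k + 1]
    } else {
      h00 <- 2 * u^3 - 3 * u^2 + 1
      h10 <- u^3 - 2 * u^2 + u
      h01 <- -2 * u^3 + 3 * u^2
      h11 <- u^3 - u^2
      h00 * f[, k] + h10 * h * m[, k] + h01 * f[, k + 1] + h11 * h * m[, k + 1]
    }
    v[v < 0] <- 0
    matrix(v, d[1], d[2])
  }
  frames <- lapply(query_times, function(tq)
    frame(interp_one(tq), pixel_pitch = pitch, time_tag = tq))
  frame_sequence(frames, as.numeric(query_times))
}

#' Decode fidelity metrics
#'
#' Normalised root-mean-square error and Pearson correlation between a
#' decoded frame and its ground truth, computed over the interior region
#' (a border of `border` pixels is excluded, where circular-convolution
#' wraparound from the decode filter concentrates).
#' `NRMSE = RMS(decoded - truth) / (max(truth) - min(truth))`.
#'
#' @param decoded,truth frames (or matrices) of equal shape.
#' @param border border width in pixels excluded from the metrics.
#' @return List with elements `nrmse` and `pearson_r`.
#' @export
fidelity <- function(decoded, truth, border = 5) {
  a <- pixel_matrix(decoded); b <- pixel_matrix(truth)
  if (!identical(dim(a), dim(b)))
    stop_validation("decoded and truth must have the same shape")
  if (border < 0 || 2 * border >= min(dim(a)))
    stop_validation("'border' leaves no interior region")
  ii <- (border + 1):(nrow(a) - border)
  jj <- (border + 1):(ncol(a) - border)
  a <- a[ii, jj]; b <- b[ii, jj]
  rng <- max(b) - min(b)
  if (rng == 0)
    stop_validation("nrmse undefined: truth has zero intensity range")
  list(nrmse = sqrt(mean((a - b)^2)) / rng,
       pearson_r = stats::cor(as.vector(a), as.vector(b)))
}

#' Channel crosstalk matrix of a decoded sequence
#'
#' Quantifies how much of each truth channel leaks into each decoded frame:
#' every decoded frame is regressed (least squares, border-excluded) onto
#' the set of truth frames, giving entry `(i, j)` = the coefficient of
#' truth `i` in decoded `j`. A perfect, crosstalk-free decode gives the
#' identity matrix. All-zero truth channels cannot receive a coefficient
#' and get a zero row.
#'
#' @param truth_frames,decoded_frames lists of equally many, equally-shaped
#'   frames (or matrices).
#' @param border border width excluded from the projection.
#' @return An `N x N` numeric matrix.
#' @export
crosstalk_matrix <- function(truth_frames, decoded_frames, border = 5) {
  n <- length(truth_frames)
  if (length(decoded_frames) != n)
    stop_validation("truth and decoded lists must have equal length")
  d <- dim(pixel_matrix(truth_frames[[1]]))
  ii <- (border + 1):(d[1] - border)
  jj <- (border + 1):(d[2] - border)
  vec <- function(x) {
    px <- pixel_matrix(x)
    if (!identical(dim(px), d)) stop_validation("shape mismatch in crosstalk input")
    as.vector(px[ii, jj])
  }
  x <- vapply(truth_frames, vec, numeric(length(ii) * length(jj)))
  y <- vapply(decoded_frames, vec, numeric(length(ii) * length(jj)))
  nrm <- colSums(x^2)
  keep <- nrm > 1e-12 * max(nrm)   # blank channels cannot receive a coefficient
  out <- matrix(0, n, n)
  if (any(keep)) {
    qrx <- qr(x[, keep, drop = FALSE])
    out[keep, ] <- qr.coef(qrx, y)
  }
  out
}
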