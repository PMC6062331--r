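#' Image frame with physical pixel pitch
#'
#' A `frame` is the basic image container of the package: a nonnegative 2D
#' intensity array together with the physical pixel pitch (mm/pixel) and an
#' optional acquisition time tag (fs). It is both the input to the encoder
#' and the output of the decoder. The coordinate convention is row-major with
#' the origin at the top-left pixel: `x` is the 0-based column index, `y` the
#' 0-based row index, and the carrier phase reference sits at pixel (0, 0).
#'
#' @param pixels numeric matrix of nonnegative intensities, at least 8 x 8.
#' @param pixel_pitch physical size of one pixel in mm (> 0).
#' @param time_tag optional acquisition time in fs, or `NULL`.
#' @return An object of class `frame`.
#' @examples
#' f <- frame(matrix(1, 16, 16), pixel_pitch = 0.007)
#' dim(f)
#' @export
frame <- function(pixels, pixel_pitch = 1, time_tag = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop_validation("'pixels' must be a numeric matrix")
  if (any(!is.finite(pixels)))
    stop_validation("frame pixels contain non-finite values")
  if (any(pixels < 0))
    stop_validation("frame pixels must be nonnegative")
  if (nrow(pixels) < 8 || ncol(pixels) < 8)
    stop_validation("frame must be at least 8 x 8 pixels, got ",
                    nrow(pixels), " x ", ncol(pixels))
  if (!is_scalar_number(pixel_pitch) || pixel_pitch <= 0)
    stop_validation("'pixel_pitch' must be a positive number (mm/pixel)")
  if (!is.null(time_tag) && !is_scalar_number(time_tag))
    stop_validation("'time_tag' must be NULL or a finite number (fs)")
  structure(
    list(pixels = unname(pixels) * 1.0, pixel_pitch = pixel_pitch,
         time_tag = time_tag),
    class = "frame"
  )
}

#' Coerce to a frame
#'
#' Matrices are wrapped with the supplied pitch; frames pass through.
#'
#' @param x matrix or `frame`.
#' @param pixel_pitch pixel pitch in mm used when `x` is a bare matrix.
#' @return A `frame`.
#' @export
as_frame <- function(x, pixel_pitch = 1) {
  if (inherits(x, "frame")) return(x)
  frame(x, pixel_pitch = pixel_pitch)
}

# Internal: pull a plain pixel matrix out of frame / exposure / matrix input.
pixel_matrix <- function(x) {
  if (inherits(x, c("frame", "multiplexed_exposure"))) x$pixels
  else if (is.matrix(x) && is.numeric(x)) x
  else stop_validation("expected a frame, multiplexed exposure, or matrix")
}

pitch_of <- function(x, default = 1) {
  if (inherits(x, "frame")) x$pixel_pitch
  else if (inherits(x, "multiplexed_exposure")) x$pixel_pitch
  else default
}

#' @export
dim.frame <- function(x) dim(x$pixels)

#' @export
print.frame <- function(x, ...) {
  cat(sprintf("<frame> %d x %d px, pitch %.4g mm/px (FOV %.3g x %.3g mm)",
              nrow(x$pixels), ncol(x$pixels), x$pixel_pitch,
              nrow(x$pixels) * x$pixel_pitch, ncol(x$pixels) * x$pixel_pitch))
  if (!is.null(x$time_tag)) cat(sprintf(", t = %.6g fs", x$time_tag))
  cat(sprintf("\n  intensity range [%.4g, %.4g]\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Display a frame as an image
#'
#' Renders the intensity matrix in the package's top-left-origin convention
#' with physical axes in mm.
#'
#' @param x a `frame`.
#' @param main plot title.
#' @param col color palette.
#' @param ... passed to [graphics::image()].
#' @export
plot.frame <- function(x, main = "frame",
                       col = grDevices::gray.colors(256, 0, 1), ...) {
  px <- x$pixels
  # image() draws x along rows; transpose so image x-axis = columns
  xs <- (seq_len(ncol(px)) - 0.5) * x$pixel_pitch
  ys <- (seq_len(nrow(px)) - 0.5) * x$pixel_pitch
  graphics::image(xs, ys, t(px[nrow(px):1, , drop = FALSE]),
                  col = col, xlab = "x (mm)", ylab = "y (mm)",
                  main = main, useRaster = TRUE, ...)
  invisible(x)
}
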