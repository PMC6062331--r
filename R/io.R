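# TIFF image I/O and YAML configuration files. Integer data round-trips
# bit-exactly; float frames are stored as normalised 32-bit float TIFF with
# the scale recorded in a JSON sidecar ("<path>.json"), together with pixel
# pitch, time tags and (for exposures) the auto-exposure gain.

sidecar_path <- function(path) paste0(path, ".json")

#' Write frames or an exposure to (multi-page) TIFF
#'
#' A single frame becomes a single-page TIFF; a list or
#' [frame_sequence()] becomes a multi-page TIFF with page order preserved.
#' Integer-valued data (e.g. a [compose()] exposure) is written losslessly
#' into an 8- or 16-bit container; other data is written as 32-bit float,
#' normalised to `[0, 1]` with the scale stored in the JSON sidecar.
#'
#' @param x a [frame()], list of frames, [frame_sequence()], or
#'   [compose()] exposure.
#' @param path output file path.
#' @param bits integer container size, 8 or 16 (ignored for float data).
#' @param sidecar write the JSON metadata sidecar next to the TIFF.
#' @return `path`, invisibly.
#' @export
write_frames <- function(x, path, bits = 16, sidecar = TRUE) {
  if (!bits %in% c(8, 16)) stop_validation("'bits' must be 8 or 16")
  meta <- list()
  if (inherits(x, "multiplexed_exposure")) {
    meta$kind <- "exposure"
    meta$bit_depth <- x$sensor$bit_depth
    meta$gain <- x$gain
    meta$pixel_pitch <- x$pixel_pitch
    pages <- list(x$pixels)
  } else {
    if (inherits(x, "frame_sequence")) {
      meta$times <- x$times
      x <- x$frames
    }
    if (inherits(x, "frame") || is.matrix(x)) x <- list(x)
    x <- lapply(x, as_frame)
    meta$pixel_pitch <- x[[1]]$pixel_pitch
    tt <- lapply(x, function(f) f$time_tag)
    if (is.null(meta$times) && !any(vapply(tt, is.null, logical(1))))
      meta$times <- unlist(tt)
    pages <- lapply(x, function(f) f$pixels)
  }
  integerish <- all(vapply(pages, function(p)
    max(p) < 2^bits && all(p == floor(p)), logical(1)))
  if (integerish) {
    meta$kind <- meta$kind %||% "integer"
    meta$scale <- 2^bits - 1
    out <- lapply(pages, function(p) p / (2^bits - 1))
    tiff::writeTIFF(out, path, bits.per.sample = bits, compression = "none")
  } else {
    meta$kind <- "float"
    meta$scale <- max(vapply(pages, max, numeric(1)))
    if (meta$scale <= 0) meta$scale <- 1
    out <- lapply(pages, function(p) p / meta$scale)
    tiff::writeTIFF(out, path, bits.per.sample = 32, compression = "none")
  }
  if (sidecar)
    jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read frames from a (multi-page) grayscale TIFF
#'
#' Reads 8/16-bit integer or 32-bit float grayscale TIFF files written by
#' [write_frames()] (or other software). Integer data is returned exactly;
#' float data is rescaled by the sidecar's recorded scale when present.
#' RGB/multi-channel TIFFs are rejected.
#'
#' @param path TIFF file path.
#' @param pixel_pitch pixel pitch in mm; overrides the sidecar value.
#' @return A list of [frame()] objects, one per page, with time tags
#'   restored from the sidecar when available.
#' @export
read_frames <- function(path, pixel_pitch = NULL) {
  if (!file.exists(path)) stop_validation("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  meta <- if (file.exists(sidecar_path(path)))
    jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE) else list()
  pitch <- pixel_pitch %||% meta$pixel_pitch %||% 1
  out <- vector("list", length(pages))
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    if (length(dim(p)) == 3L)
      stop_validation("RGB or multi-channel TIFF is not supported; ",
                      "expected a grayscale image (page ", i, ")")
    bps <- attr(p, "bits.per.sample") %||% 16
    p <- matrix(as.numeric(p), nrow(p), ncol(p))
    if (bps < 32) {                       # 8/16-bit pages are unsigned ints
      p <- round(p * (2^bps - 1))         # undo readTIFF's [0, 1] scaling
    } else {
      p <- p * (meta$scale %||% 1)
    }
    tt <- if (!is.null(meta$times) && length(meta$times) >= i)
      meta$times[i] else NULL
    out[[i]] <- frame(p, pixel_pitch = pitch, time_tag = tt)
  }
  out
}

#' Write a codebook to a YAML file
#'
#' Plain-text key-value representation: the filter and baseband radii plus
#' one `nu_x, nu_y, m, phi` entry per carrier (frequencies in cycles/pixel).
#' Round-trips losslessly through [read_codebook()].
#'
#' @param cb a [codebook()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_codebook <- function(cb, path) {
  if (!inherits(cb, "codebook")) stop_validation("'cb' must be a codebook")
  doc <- list(
    filter_radius = cb$filter_radius,
    baseband_radius = cb$baseband_radius,
    carriers = lapply(cb$codes, function(cc)
      list(nu_x = cc$nu[1], nu_y = cc$nu[2], m = cc$m, phi = cc$phi))
  )
  yaml::write_yaml(doc, path, precision = 17)
  invisible(path)
}

#' Read and validate a codebook from a YAML file
#'
#' All [codebook()] invariants are enforced on read: Nyquist-violating,
#' duplicate, or overlapping carriers are rejected with the offending
#' indices named. Unknown keys are rejected.
#'
#' @param path YAML file written by [write_codebook()] (or by hand).
#' @return A [codebook()].
#' @export
read_codebook <- function(path) {
  if (!file.exists(path)) stop_validation("no such file: ", path)
  doc <- yaml::read_yaml(path)
  allowed <- c("filter_radius", "baseband_radius", "carriers")
  extra <- setdiff(names(doc), allowed)
  if (length(extra) > 0)
    stop_validation("unknown codebook keys: ", paste(extra, collapse = ", "))
  if (is.null(doc$filter_radius) || is.null(doc$carriers))
    stop_validation("codebook file must define 'filter_radius' and 'carriers'")
  codes <- lapply(seq_along(doc$carriers), function(i) {
    cc <- doc$carriers[[i]]
    extra <- setdiff(names(cc), c("nu_x", "nu_y", "m", "phi"))
    if (length(extra) > 0)
      stop_validation("carrier ", i, ": unknown keys ",
                      paste(extra, collapse = ", "))
    tryCatch(
      carrier_code(c(cc$nu_x, cc$nu_y), m = cc$m %||% 1, phi = cc$phi %||% 0),
      error = function(e)
        stop_validation("carrier ", i, ": ", conditionMessage(e)))
  })
  codebook(codes, filter_radius = doc$filter_radius,
           baseband_radius = doc$baseband_radius %||%
             (2 * doc$filter_radius))
}

# Allowed RunConfig keys, per CLI subcommand.
run_config_keys <- list(
  seed = NA, log_level = NA,
  plan = c("n_frames", "filter_radius", "baseband_radius", "otf_cutoff",
           "min_separation", "guard_factor", "out"),
  encode = c("frames", "codebook", "out", "bit_depth", "full_well",
             "read_noise_sigma", "shot_noise"),
  decode = c("exposure", "codebook", "out", "window", "window_param",
             "detect"),
  simulate = c("pump_fwhm", "pump_waist", "divergence_angle", "n_refr",
               "tau_relax", "extent", "shape", "voxel", "read_delays",
               "out"),
  eval = c("truth", "decoded", "report", "border")
)

#' Read and validate a run configuration file
#'
#' YAML key-value configuration for the command-line interface: optional
#' global `seed` and `log_level` plus one section per subcommand (`plan`,
#' `encode`, `decode`, `simulate`, `eval`). Unknown keys anywhere are
#' rejected, so configurations round-trip losslessly.
#'
#' @param path YAML file path.
#' @return Named list of validated configuration values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_validation("no such file: ", path)
  doc <- yaml::read_yaml(path)
  extra <- setdiff(names(doc), names(run_config_keys))
  if (length(extra) > 0)
    stop_validation("unknown config keys: ", paste(extra, collapse = ", "))
  for (sec in setdiff(names(doc), c("seed", "log_level"))) {
    bad <- setdiff(names(doc[[sec]]), run_config_keys[[sec]])
    if (length(bad) > 0)
      stop_validation("unknown keys in '", sec, "': ",
                      paste(bad, collapse = ", "))
  }
  if (!is.null(doc$seed) && !is_scalar_number(doc$seed))
    stop_validation("'seed' must be a number")
  doc
}
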