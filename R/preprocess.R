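#' Rectangular region of interest
#'
#' 0-based, half-open on both axes: rows `[row0, row0 + height)`, columns
#' `[col0, col0 + width)`. Constraining all computations to a user-defined
#' ROI keeps the Fourier processing cheap and is applied uniformly to the
#' dark, bright, reference and sample images.
#'
#' @param row0,col0 0-based top-left corner.
#' @param height,width Extent in pixels, each at least 16.
#' @return An object of class `shi_roi`.
#' @export
roi <- function(row0, col0, height, width) {
  vals <- c(row0, col0, height, width)
  stopifnot(length(vals) == 4L, all(is.finite(vals)), all(vals == round(vals)))
  if (height < 16L || width < 16L) {
    stop("ROI must be at least 16 x 16 pixels", call. = FALSE)
  }
  if (row0 < 0L || col0 < 0L) stop("ROI origin must be non-negative", call. = FALSE)
  structure(list(row0 = as.integer(row0), col0 = as.integer(col0),
                 height = as.integer(height), width = as.integer(width)),
            class = "shi_roi")
}

#' @rdname roi
#' @param frame_or_pixels Frame or matrix whose full extent the ROI should cover.
#' @export
full_roi <- function(frame_or_pixels) {
  d <- if (inherits(frame_or_pixels, "shi_frame")) dim(frame_or_pixels$pixels)
       else dim(frame_or_pixels)
  roi(0L, 0L, d[1], d[2])
}

#' Persist / restore an ROI as YAML
#'
#' The ROI is saved to file once and re-applied identically on every run,
#' so repeated processing of one measurement is deterministic.
#'
#' @param x A [roi()].
#' @param path YAML file path.
#' @export
save_roi <- function(x, path) {
  stopifnot(inherits(x, "shi_roi"))
  yaml::write_yaml(list(roi = unclass(x)), path)
  invisible(path)
}

#' @rdname save_roi
#' @export
load_roi <- function(path) {
  y <- yaml::read_yaml(path)$roi
  roi(y$row0, y$col0, y$height, y$width)
}

#' Crop a frame to an ROI
#'
#' @param x A [frame()] (or plain matrix).
#' @param region A [roi()] fully contained in the frame.
#' @return Cropped frame (or matrix), values bit-equal to the source window.
#' @export
crop <- function(x, region) {
  stopifnot(inherits(region, "shi_roi"))
  px <- if (inherits(x, "shi_frame")) x$pixels else x
  if (region$row0 + region$height > nrow(px)) {
    stop(sprintf("ROI bottom edge %d exceeds frame height %d",
                 region$row0 + region$height, nrow(px)), call. = FALSE)
  }
  if (region$col0 + region$width > ncol(px)) {
    stop(sprintf("ROI right edge %d exceeds frame width %d",
                 region$col0 + region$width, ncol(px)), call. = FALSE)
  }
  out <- px[(region$row0 + 1L):(region$row0 + region$height),
            (region$col0 + 1L):(region$col0 + region$width), drop = FALSE]
  if (inherits(x, "shi_frame")) {
    frame(out, category = x$category, angle_deg = x$angle_deg, index = x$index)
  } else out
}

#' Dark / bright flat-field correction
#'
#' Standard two-point detector correction
#' \deqn{T = (I - D) / (B - D)}
#' mapping the bright frame to unity and the dark frame to zero, removing
#' detector offset and gain/illumination structure. Pixels whose
#' bright-minus-dark denominator is at or below `eps`, and saturated
#' pixels (at the 16-bit ceiling in the bright or corrected frame), are
#' flagged invalid in the mask and set to 0 so downstream FFTs stay
#' finite. The correction is invariant to a global detector gain.
#'
#' @param x Frame (or matrix) to correct.
#' @param dark,bright Dark and bright frames (or matrices) of the same shape.
#' @param eps Denominator guard; default `1e-6 * max(bright)`.
#' @return An object of class `shi_corrected` with fields `pixels` (the
#'   normalized transmission, nominally in \[0, 1\]) and `valid` (logical
#'   mask).
#' @export
flat_field <- function(x, dark, bright, eps = NULL) {
  px <- if (inherits(x, "shi_frame")) x$pixels else as_pixel_matrix(x)
  d  <- if (inherits(dark, "shi_frame")) dark$pixels else as_pixel_matrix(dark)
  b  <- if (inherits(bright, "shi_frame")) bright$pixels else as_pixel_matrix(bright)
  if (!identical(dim(px), dim(d)) || !identical(dim(px), dim(b))) {
    stop("frame, dark and bright must share one shape", call. = FALSE)
  }
  if (is.null(eps)) eps <- 1e-6 * max(b)
  stopifnot(eps > 0)
  denom <- b - d
  valid <- denom > eps
  # saturation at the 16-bit ceiling would fake visibility loss downstream
  valid <- valid & b < 65535 & px < 65535
  out <- matrix(0, nrow(px), ncol(px))
  out[valid] <- (px[valid] - d[valid]) / denom[valid]
  structure(list(pixels = out, valid = valid), class = "shi_corrected")
}

#' @export
print.shi_corrected <- function(x, ...) {
  cat(sprintf("<shi_corrected> %d x %d px, %.1f%% valid\n",
              nrow(x$pixels), ncol(x$pixels), 100 * mean(x$valid)))
  invisible(x)
}

#' Screen out sparse or corrupted frames
#'
#' Repeated exposures occasionally contain dropped or partially
#' transferred frames. A frame is rejected when its mean intensity
#' deviates from the median of the per-frame means by more than
#' `rel_threshold` as a fraction of that median. Survivor order is
#' preserved.
#'
#' @param stack A [frame_stack()].
#' @param rel_threshold Relative deviation threshold in (0, 1).
#' @return A list with `stack` (survivors) and `rejected` (integer indices
#'   into the input stack, possibly empty).
#' @export
screen_corrupted <- function(stack, rel_threshold = 0.5) {
  stopifnot(inherits(stack, "shi_stack"),
            rel_threshold > 0, rel_threshold < 1)
  means <- vapply(stack$frames, function(f) mean(f$pixels), numeric(1))
  med <- stats::median(means)
  bad <- which(abs(means - med) > rel_threshold * abs(med))
  if (length(bad) == length(means)) {
    stop("no usable frames: every frame deviates beyond the threshold", call. = FALSE)
  }
  keep <- setdiff(seq_along(means), bad)
  list(stack = frame_stack(stack$frames[keep]), rejected = bad)
}
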