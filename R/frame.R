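#' Detector frame
#'
#' A `shi_frame` wraps a single 2-D detector image together with its
#' acquisition category. The four categories follow the standard
#' single-shot harmonic-imaging protocol: `dark` (source off, detector
#' offset only), `bright` (source on, no mask, no sample), `reference`
#' (mask only) and `sample` (mask plus object).
#'
#' @param pixels Numeric matrix of detector counts (ADU). Both dimensions
#'   must be at least 8 and all values finite and non-negative.
#' @param category One of `"dark"`, `"bright"`, `"reference"`, `"sample"`.
#' @param angle_deg Optional projection angle in degrees; present only for
#'   frames belonging to a CT scan.
#' @param index Integer repeat index within a stack (1-based).
#' @return An object of class `shi_frame` with fields `pixels`, `category`,
#'   `angle_deg` and `index`.
#' @export
frame <- function(pixels, category = c("dark", "bright", "reference", "sample"),
                  angle_deg = NULL, index = 1L) {
  category <- match.arg(category)
  pixels <- as_pixel_matrix(pixels)
  if (any(dim(pixels) < 8L)) {
    stop("frame must be at least 8 x 8 pixels, got ",
         paste(dim(pixels), collapse = " x "), call. = FALSE)
  }
  if (!is.null(angle_deg)) {
    stopifnot(is.numeric(angle_deg), length(angle_deg) == 1L, is.finite(angle_deg))
    angle_deg <- as.numeric(angle_deg)
  }
  structure(
    list(pixels = pixels, category = category,
         angle_deg = angle_deg, index = as.integer(index)),
    class = "shi_frame"
  )
}

as_pixel_matrix <- function(pixels) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("pixels must be a numeric matrix", call. = FALSE)
  }
  if (!all(is.finite(pixels))) {
    stop("pixels contain non-finite values", call. = FALSE)
  }
  storage.mode(pixels) <- "double"
  pixels
}

#' @export
print.shi_frame <- function(x, ...) {
  cat(sprintf("<shi_frame> %s  %d x %d px  range [%.4g, %.4g]%s\n",
              x$category, nrow(x$pixels), ncol(x$pixels),
              min(x$pixels), max(x$pixels),
              if (is.null(x$angle_deg)) "" else sprintf("  angle %.3f deg", x$angle_deg)))
  invisible(x)
}

#' Ordered stack of same-shape frames
#'
#' @param frames List of [frame()] objects, all of the same shape and
#'   category.
#' @return An object of class `shi_stack`.
#' @export
frame_stack <- function(frames) {
  if (length(frames) == 0L) stop("frame stack must be non-empty", call. = FALSE)
  if (!all(vapply(frames, inherits, logical(1), "shi_frame"))) {
    stop("all elements must be shi_frame objects", call. = FALSE)
  }
  shp <- dim(frames[[1L]]$pixels)
  cat0 <- frames[[1L]]$category
  for (i in seq_along(frames)) {
    if (!identical(dim(frames[[i]]$pixels), shp)) {
      stop(sprintf("frame %d has shape %s, expected %s", i,
                   paste(dim(frames[[i]]$pixels), collapse = "x"),
                   paste(shp, collapse = "x")), call. = FALSE)
    }
    if (!identical(frames[[i]]$category, cat0)) {
      stop(sprintf("frame %d has category '%s', expected '%s'",
                   i, frames[[i]]$category, cat0), call. = FALSE)
    }
  }
  structure(list(frames = frames, category = cat0, shape = shp),
            class = "shi_stack")
}

#' @export
length.shi_stack <- function(x) length(x$frames)

#' @export
print.shi_stack <- function(x, ...) {
  cat(sprintf("<shi_stack> %d %s frame(s), %d x %d px\n",
              length(x$frames), x$category, x$shape[1], x$shape[2]))
  invisible(x)
}

#' Pixel-wise mean of a frame stack
#'
#' Averaging repeated exposures raises SNR before contrast retrieval; the
#' accumulation is done in double precision regardless of the on-disk bit
#' depth, and the result keeps the stack category. The operation is
#' permutation-invariant over frame order.
#'
#' @param stack A [frame_stack()].
#' @return A single [frame()] holding the arithmetic per-pixel mean.
#' @export
average_stack <- function(stack) {
  stopifnot(inherits(stack, "shi_stack"))
  n <- length(stack$frames)
  acc <- matrix(0, stack$shape[1], stack$shape[2])
  for (f in stack$frames) acc <- acc + f$pixels
  frame(acc / n, category = stack$category,
        angle_deg = stack$frames[[1L]]$angle_deg)
}

#' Convergence of the cumulative frame average
#'
#' For a stack of N repeated exposures, computes for every n = 1..N the
#' root-mean-square error between the cumulative average of the first n
#' frames and the average of all N frames. The curve quantifies how fast
#' averaging stabilises; its final entry is exactly zero by construction
#' (the full cumulative mean and the reference mean are the same sum).
#'
#' @param stack A [frame_stack()] with at least 2 frames.
#' @return A data frame with columns `n` and `rmse`, of N rows.
#' @export
rmse_convergence <- function(stack) {
  stopifnot(inherits(stack, "shi_stack"))
  n_tot <- length(stack$frames)
  if (n_tot < 2L) stop("rmse_convergence needs a stack of at least 2 frames", call. = FALSE)
  acc <- matrix(0, stack$shape[1], stack$shape[2])
  sums <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    acc <- acc + stack$frames[[i]]$pixels
    sums[[i]] <- acc
  }
  full_mean <- sums[[n_tot]] / n_tot
  rmse <- vapply(seq_len(n_tot), function(i) {
    sqrt(mean((sums[[i]] / i - full_mean)^2))
  }, numeric(1))
  data.frame(n = seq_len(n_tot), rmse = rmse)
}
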