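#' Centered 2-D Fourier spectrum of a corrected frame
#'
#' The mesh pattern of the mask concentrates the image information into a
#' lattice of harmonic peaks in frequency space; all contrast retrieval
#' happens on this spectrum. The zero-frequency bin is placed at the array
#' center (row/col `floor(n/2)` 0-based).
#'
#' @param x A `shi_corrected`, [frame()], or numeric matrix.
#' @param window `"none"` (default) or `"hann"`; a Hann taper can be
#'   applied for ROIs with strong edge discontinuities to limit spectral
#'   leakage.
#' @return An object of class `shi_spectrum` with complex `values` and the
#'   source `shape`.
#' @export
forward_spectrum <- function(x, window = c("none", "hann")) {
  window <- match.arg(window)
  px <- if (inherits(x, "shi_corrected")) x$pixels
        else if (inherits(x, "shi_frame")) x$pixels
        else x
  if (!is.matrix(px) || !all(is.finite(px))) {
    stop("forward_spectrum needs a finite 2-D input", call. = FALSE)
  }
  if (window == "hann") {
    h1 <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nrow(px)) - 1) / (nrow(px) - 1))
    h2 <- 0.5 - 0.5 * cos(2 * pi * (seq_len(ncol(px)) - 1) / (ncol(px) - 1))
    px <- px * outer(h1, h2)
  }
  structure(list(values = fftshift2(stats::fft(px)), shape = dim(px)),
            class = "shi_spectrum")
}

#' @rdname forward_spectrum
#' @param spectrum A `shi_spectrum`.
#' @return `inverse_spectrum()` returns the complex image whose transform
#'   the spectrum is; real inputs round-trip within 1e-10 relative error.
#' @export
inverse_spectrum <- function(spectrum) {
  stopifnot(inherits(spectrum, "shi_spectrum"))
  n <- prod(spectrum$shape)
  stats::fft(ifftshift2(spectrum$values), inverse = TRUE) / n
}

#' @export
print.shi_spectrum <- function(x, ...) {
  cat(sprintf("<shi_spectrum> %d x %d bins\n", x$shape[1], x$shape[2]))
  invisible(x)
}

# Centered-array index (1-based) of the peak carrying label (m, n), given
# the fundamental spacings in bins. Labels follow the displacement-sign
# convention: (+1, 0) denotes the harmonic whose differential phase grows
# positive for a pattern displacement toward +x (column) direction; with
# the e^{-i2pi} DFT convention of stats::fft that is the bin at negative
# column frequency, hence the sign flip below.
label_center <- function(label, f_col, f_row, shape) {
  cb <- center_bin(shape)
  c(cb[1] - round(label[2] * f_row), cb[2] - round(label[1] * f_col))
}

#' Detect the harmonic peak lattice of a reference spectrum
#'
#' Locates the nine harmonics `(m, n)` in `{-1, 0, 1}^2` produced by the
#' periodic mask: the fundamental spacing is found by a peak search along
#' each frequency axis (restricted to the neighborhood predicted by
#' `expected_period_px` when given, else a global search per axis band),
#' then each first/second-order peak is snapped to the magnitude maximum
#' within a +/-2-bin window around its predicted lattice position. This
#' residual-displacement compensation absorbs the small shifts that
#' finite source size, sampling and mask/detector misalignment introduce.
#'
#' The filter half-width `band_limit` is set to the midpoint between
#' adjacent harmonics (floor of half the measured inter-peak spacing),
#' shrunk if needed so every extraction window stays inside the spectrum.
#' The projected mask period must satisfy the Nyquist constraint
#' `d >= 3` detector pixels or an error is raised.
#'
#' @param spectrum Spectrum of a reference (mask-only) corrected image.
#' @param expected_period_px Optional projected mask period in detector
#'   pixels (must be >= 3); restricts the fundamental search window.
#' @param noise_rel Detection threshold: every harmonic peak magnitude
#'   must exceed `noise_rel` times the zero-frequency magnitude.
#' @return An object of class `shi_harmonic_meta` with fields `peaks`
#'   (named by label, each with `label`, `center` as 1-based array index
#'   into the centered spectrum, and `magnitude`), `band_limit`, measured
#'   periods `d_x`, `d_y` and their minimum `d`, and the source `shape`.
#' @export
detect_peaks <- function(spectrum, expected_period_px = NULL, noise_rel = 0.005) {
  stopifnot(inherits(spectrum, "shi_spectrum"))
  if (!is.null(expected_period_px) && expected_period_px < 3) {
    stop("Nyquist violation: expected projected period ", expected_period_px,
         " px is below the minimum of 3 detector pixels", call. = FALSE)
  }
  mag <- Mod(spectrum$values)
  shape <- spectrum$shape
  cb <- center_bin(shape)
  dc_mag <- mag[cb[1], cb[2]]

  find_axis_peak <- function(axis) {
    # axis "col": search along the column-frequency axis; "row" likewise
    if (axis == "col") {
      if (!is.null(expected_period_px)) {
        f0 <- round(shape[2] / expected_period_px)
        cols <- intersect(cb[2] + f0 + (-2:2), seq_len(shape[2]))
      } else {
        cols <- (cb[2] + 3):shape[2]
      }
      rows <- intersect(cb[1] + (-2:2), seq_len(shape[1]))
    } else {
      if (!is.null(expected_period_px)) {
        f0 <- round(shape[1] / expected_period_px)
        rows <- intersect(cb[1] + f0 + (-2:2), seq_len(shape[1]))
      } else {
        rows <- (cb[1] + 3):shape[1]
      }
      cols <- intersect(cb[2] + (-2:2), seq_len(shape[2]))
    }
    sub <- mag[rows, cols, drop = FALSE]
    idx <- arrayInd(which.max(sub), dim(sub))
    c(rows[idx[1]], cols[idx[2]])
  }

  px_col <- find_axis_peak("col")
  px_row <- find_axis_peak("row")
  f_col <- abs(px_col[2] - cb[2])
  f_row <- abs(px_row[1] - cb[1])
  if (f_col == 0 || f_row == 0) {
    stop("mask not resolved: no off-center fundamental peak found", call. = FALSE)
  }
  d_x <- shape[2] / f_col
  d_y <- shape[1] / f_row
  d <- min(d_x, d_y)
  if (d < 3) {
    stop(sprintf(
      "Nyquist violation: fitted projected period %.3f px is below 3 detector pixels", d),
      call. = FALSE)
  }

  snap <- function(pred) {
    rows <- intersect(pred[1] + (-2:2), seq_len(shape[1]))
    cols <- intersect(pred[2] + (-2:2), seq_len(shape[2]))
    sub <- mag[rows, cols, drop = FALSE]
    idx <- arrayInd(which.max(sub), dim(sub))
    c(rows[idx[1]], cols[idx[2]])
  }

  peaks <- list()
  for (label in HARMONIC_LABELS) {
    if (all(label == 0L)) {
      ctr <- cb
    } else {
      ctr <- snap(label_center(label, f_col, f_row, shape))
    }
    pk_mag <- mag[ctr[1], ctr[2]]
    if (pk_mag < noise_rel * dc_mag) {
      stop(sprintf("mask not resolved: harmonic (%d,%d) below the noise floor",
                   label[1], label[2]), call. = FALSE)
    }
    peaks[[label_key(label)]] <- list(label = as.integer(label),
                                      center = as.integer(ctr),
                                      magnitude = pk_mag)
  }

  # spacing re-measured between snapped symmetric first-order peaks
  sp_col <- abs(peaks[["+1+0"]]$center[2] - peaks[["-1+0"]]$center[2]) / 2
  sp_row <- abs(peaks[["+0+1"]]$center[1] - peaks[["+0-1"]]$center[1]) / 2
  band_limit <- floor(min(sp_col, sp_row) / 2)
  for (p in peaks) {
    fit <- min(p$center[1] - 1L, shape[1] - p$center[1],
               p$center[2] - 1L, shape[2] - p$center[2])
    band_limit <- min(band_limit, fit)
  }
  if (band_limit < 1L) {
    stop("harmonic peaks too close to the spectrum edge for any band limit",
         call. = FALSE)
  }

  structure(list(peaks = peaks, band_limit = as.integer(band_limit),
                 d = d, d_x = d_x, d_y = d_y, shape = shape),
            class = "shi_harmonic_meta")
}

#' @export
print.shi_harmonic_meta <- function(x, ...) {
  cat(sprintf("<shi_harmonic_meta> %d peaks, band_limit %d, period %.2f px (%.2f x, %.2f y)\n",
              length(x$peaks), x$band_limit, x$d, x$d_x, x$d_y))
  invisible(x)
}

#' Extract one band-limited harmonic as a complex image
#'
#' Cuts the square `(2*band_limit+1)^2` window centered on a harmonic
#' peak, re-centers it onto zero frequency and inverse-transforms it. The
#' modulus of the result carries the local pattern amplitude of that
#' harmonic and the argument its phase; all harmonics of one spectrum
#' share this fixed output size, which is what makes the per-harmonic
#' images mutually comparable. Values are normalized so that the `(0,0)`
#' harmonic of a constant image equals that constant.
#'
#' @param spectrum A `shi_spectrum`.
#' @param peak A peak entry from [detect_peaks()] (fields `label`,
#'   `center`), or an integer label `c(m, n)` together with `meta`.
#' @param band_limit Half-width of the extraction window in bins.
#' @return An object of class `shi_harmonic` with fields `label`, complex
#'   `values` of dimension `(2*band_limit+1)^2`, `band_limit` and
#'   `source_shape`.
#' @export
extract_harmonic <- function(spectrum, peak, band_limit) {
  stopifnot(inherits(spectrum, "shi_spectrum"))
  b <- as.integer(band_limit)
  ctr <- peak$center
  shape <- spectrum$shape
  if (ctr[1] - b < 1L || ctr[1] + b > shape[1] ||
      ctr[2] - b < 1L || ctr[2] + b > shape[2]) {
    stop(sprintf(
      "extraction window around (%d,%d) clipped by the spectrum edge; use a smaller band limit than %d",
      ctr[1], ctr[2], b), call. = FALSE)
  }
  win <- spectrum$values[(ctr[1] - b):(ctr[1] + b),
                         (ctr[2] - b):(ctr[2] + b), drop = FALSE]
  vals <- stats::fft(ifftshift2(win), inverse = TRUE) / prod(shape)
  structure(list(label = peak$label, values = vals,
                 band_limit = b, source_shape = shape),
            class = "shi_harmonic")
}

#' @export
print.shi_harmonic <- function(x, ...) {
  cat(sprintf("<shi_harmonic> (%+d,%+d)  %d x %d px\n", x$label[1], x$label[2],
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Extract all harmonics of a spectrum using stored metadata
#'
#' Peak detection and labeling are run once on a reference image; the
#' stored centers and band limit are then applied unchanged to every
#' further reference or sample spectrum (this is the normal path for
#' sample images and for all CT angles, and guarantees that sample and
#' reference harmonics occupy corresponding frequency windows).
#'
#' @param spectrum A `shi_spectrum` with the same shape `meta` was
#'   derived from.
#' @param meta A `shi_harmonic_meta` from [detect_peaks()].
#' @return Named list (by label key, e.g. `"+1+0"`) of `shi_harmonic`.
#' @export
apply_metadata <- function(spectrum, meta) {
  stopifnot(inherits(spectrum, "shi_spectrum"),
            inherits(meta, "shi_harmonic_meta"))
  if (!identical(as.integer(spectrum$shape), as.integer(meta$shape))) {
    stop(sprintf("spectrum shape %s does not match metadata shape %s",
                 paste(spectrum$shape, collapse = "x"),
                 paste(meta$shape, collapse = "x")), call. = FALSE)
  }
  lapply(meta$peaks, function(p) extract_harmonic(spectrum, p, meta$band_limit))
}

#' Persist / restore harmonic metadata as JSON
#'
#' @param meta A `shi_harmonic_meta`.
#' @param path JSON file path (conventionally `harmonics.json` in the
#'   project `out/` directory).
#' @export
save_harmonic_meta <- function(meta, path) {
  stopifnot(inherits(meta, "shi_harmonic_meta"))
  jsonlite::write_json(list(
    shape = meta$shape, band_limit = meta$band_limit,
    d = meta$d, d_x = meta$d_x, d_y = meta$d_y,
    peaks = lapply(meta$peaks, function(p) {
      list(label = p$label, center = p$center, magnitude = p$magnitude)
    })
  ), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname save_harmonic_meta
#' @export
load_harmonic_meta <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  peaks <- lapply(j$peaks, function(p) {
    list(label = as.integer(p$label), center = as.integer(p$center),
         magnitude = as.numeric(p$magnitude))
  })
  structure(list(peaks = peaks, band_limit = as.integer(j$band_limit),
                 d = j$d, d_x = j$d_x, d_y = j$d_y,
                 shape = as.integer(j$shape)),
            class = "shi_harmonic_meta")
}
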