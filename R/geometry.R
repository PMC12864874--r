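#' Acquisition geometry
#'
#' Distances of the divergent-beam setup: source to optic (mask) `d1`,
#' source to sample `d2`, source to detector `dsd`, all in cm, plus the
#' detector pixel pitch and mask period in micrometers. In the validated
#' configuration the optic sits upstream of the sample (`d1 <= d2`); the
#' alternative order is admitted with `optic_upstream = FALSE`.
#'
#' @param d1_cm,d2_cm,dsd_cm Distances in cm, `0 < d1 <= d2 < dsd` (order
#'   of `d1`, `d2` reversed when `optic_upstream = FALSE`).
#' @param pixel_um Detector pixel size in micrometers.
#' @param mask_period_um Mask period in micrometers.
#' @param optic_upstream Logical; see above.
#' @return An object of class `shi_geometry`.
#' @export
geometry <- function(d1_cm, d2_cm, dsd_cm, pixel_um, mask_period_um,
                     optic_upstream = TRUE) {
  vals <- c(d1_cm, d2_cm, dsd_cm, pixel_um, mask_period_um)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("all geometry values must be positive and finite", call. = FALSE)
  }
  if (optic_upstream && d1_cm > d2_cm) {
    stop("optic-upstream geometry requires d1 <= d2", call. = FALSE)
  }
  if (!optic_upstream && d2_cm > d1_cm) {
    stop("optic-downstream geometry requires d2 <= d1", call. = FALSE)
  }
  if (max(d1_cm, d2_cm) >= dsd_cm) {
    stop("source-detector distance must exceed optic and sample distances",
         call. = FALSE)
  }
  g <- structure(list(d1 = d1_cm, d2 = d2_cm, dsd = dsd_cm,
                      pixel_um = pixel_um, mask_period_um = mask_period_um,
                      optic_upstream = optic_upstream),
                 class = "shi_geometry")
  d <- projected_period_px(g)
  if (d < 3) {
    stop(sprintf(
      "Nyquist violation: projected mask period %.3f px is below 3 detector pixels", d),
      call. = FALSE)
  }
  g
}

#' @export
print.shi_geometry <- function(x, ...) {
  cat(sprintf("<shi_geometry> d1=%g cm d2=%g cm dsd=%g cm pixel=%g um period=%g um (projected %.2f px)\n",
              x$d1, x$d2, x$dsd, x$pixel_um, x$mask_period_um,
              projected_period_px(x)))
  invisible(x)
}

#' Mask period as imaged on the detector, in detector pixels
#'
#' The mask pattern is magnified from the optic plane to the detector by
#' `dsd / d1`; dividing by the pixel pitch gives the projected period
#' `d`, which sets the harmonic spacing and must satisfy `d >= 3`.
#'
#' @param geom A [geometry()].
#' @return Projected period in detector pixels.
#' @export
projected_period_px <- function(geom) {
  stopifnot(inherits(geom, "shi_geometry"))
  geom$mask_period_um * (geom$dsd / geom$d1) / geom$pixel_um
}

#' Effective detector pixel size with the optic in the beam
#'
#' For reconstruction purposes the optic is absorbed into an imaginary
#' setup with a rescaled pixel: the detector pitch multiplied by the
#' ratio of the sample and optic distances, oriented with the larger
#' distance in the numerator (for the optic-upstream configuration this
#' is `d2 / d1`). Note the value grows slightly above the physical pitch;
#' the symbolic form with the inverse ratio would instead shrink it,
#' which contradicts the worked configuration this convention is pinned
#' to. The result is homogeneous of degree 1 in the pixel pitch and
#' invariant under rescaling all distances by a common factor.
#'
#' @param geom A [geometry()].
#' @return Effective pixel size in micrometers.
#' @export
effective_pixel_size <- function(geom) {
  stopifnot(inherits(geom, "shi_geometry"))
  geom$pixel_um * max(geom$d1, geom$d2) / min(geom$d1, geom$d2)
}

#' Sample-plane pixel size
#'
#' The detector pitch demagnified to the sample plane, `pixel * d2 /
#' dsd`: the true sampling distance of the object in a divergent beam.
#'
#' @param geom A [geometry()].
#' @return Sample-plane pixel size in micrometers.
#' @export
sample_plane_pixel_size <- function(geom) {
  stopifnot(inherits(geom, "shi_geometry"))
  geom$pixel_um * geom$d2 / geom$dsd
}

#' Read a processing configuration YAML
#'
#' Expected blocks: `geometry` (`d1_cm`, `d2_cm`, `dsd_cm`, `pixel_um`,
#' `mask_period_um`), optional `roi` (`row0`, `col0`, `height`, `width`),
#' optional `processing` (`band_limit`, `unwrap`, `guard`).
#'
#' @param path YAML file.
#' @return List with `geometry` (a `shi_geometry`), `roi` (a `shi_roi` or
#'   `NULL`) and `processing` (list).
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$geometry)) stop("config is missing the geometry block", call. = FALSE)
  g <- y$geometry
  geom <- geometry(g$d1_cm, g$d2_cm, g$dsd_cm, g$pixel_um, g$mask_period_um,
                   optic_upstream = !isFALSE(g$optic_upstream))
  region <- if (!is.null(y$roi)) roi(y$roi$row0, y$roi$col0, y$roi$height, y$roi$width)
  list(geometry = geom, roi = region,
       processing = if (is.null(y$processing)) list() else y$processing)
}
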