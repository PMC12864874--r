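#' Reference correction of a harmonic image
#'
#' Pixel-wise complex division of a sample harmonic by the matching
#' reference harmonic. The division removes everything contributed by the
#' mask and the illumination, leaving the sample-only complex signal
#' whose modulus carries absorption/visibility information and whose
#' argument carries the differential phase. Pixels where the reference
#' modulus falls below `guard` times its maximum are masked invalid
#' rather than divided.
#'
#' @param sample_h,ref_h `shi_harmonic` images with identical labels and
#'   shapes.
#' @param guard Relative guard threshold for the reference modulus.
#' @return An object of class `shi_ratio` with fields `label`, complex
#'   `values`, and logical `valid`.
#' @export
reference_correct <- function(sample_h, ref_h, guard = 1e-3) {
  stopifnot(inherits(sample_h, "shi_harmonic"), inherits(ref_h, "shi_harmonic"),
            guard > 0)
  if (!identical(as.integer(sample_h$label), as.integer(ref_h$label))) {
    stop(sprintf("harmonic label mismatch: sample (%+d,%+d) vs reference (%+d,%+d)",
                 sample_h$label[1], sample_h$label[2],
                 ref_h$label[1], ref_h$label[2]), call. = FALSE)
  }
  if (!identical(dim(sample_h$values), dim(ref_h$values))) {
    stop("harmonic image shapes differ", call. = FALSE)
  }
  rmod <- Mod(ref_h$values)
  valid <- rmod > guard * max(rmod)
  vals <- matrix(0 + 0i, nrow(rmod), ncol(rmod))
  vals[valid] <- sample_h$values[valid] / ref_h$values[valid]
  structure(list(label = sample_h$label, values = vals, valid = valid),
            class = "shi_ratio")
}

stop_if_label <- function(x, want_zero, what) {
  is_zero <- all(x$label == 0L)
  if (want_zero && !is_zero) {
    stop(what, " is defined only for the (0,0) harmonic, got (",
         x$label[1], ",", x$label[2], ")", call. = FALSE)
  }
  if (!want_zero && is_zero) {
    stop(what, " is undefined at the (0,0) harmonic", call. = FALSE)
  }
}

#' Absorption contrast from the fundamental harmonic
#'
#' `A = -ln |I^S_00 / I^R_00|`. The (0,0) harmonic carries no mask
#' modulation, so it is blind to small-angle refraction and diffraction
#' and its attenuation obeys Beer-Lambert: for a pure absorber the output
#' equals the optical thickness `mu * d` (dimensionless). Non-positive
#' ratios are masked invalid.
#'
#' @param ratio00 A `shi_ratio` with label `(0, 0)`.
#' @return List with the real `map` (in -ln units) and logical `valid`.
#' @export
absorption <- function(ratio00) {
  stopifnot(inherits(ratio00, "shi_ratio"))
  stop_if_label(ratio00, TRUE, "absorption")
  m <- Mod(ratio00$values)
  valid <- ratio00$valid & m > 0
  out <- matrix(0, nrow(m), ncol(m))
  out[valid] <- -log(m[valid])
  list(map = out, valid = valid)
}

#' Scattering (dark-field) contrast of a first or second order harmonic
#'
#' The sample's sub-resolution scatter blurs the mask pattern, reducing
#' the modulation visibility of the order-(m,n) harmonic relative to the
#' fundamental. The contrast is the negative log of that visibility ratio,
#' \deqn{S = -ln[ (|I^S_{mn}| / |I^S_{00}|) / (|I^R_{mn}| / |I^R_{00}|) ],}
#' so plain absorption cancels exactly through the fundamental
#' normalization and `S = 0` for a pure absorber. The same expression at
#' the diagonal labels gives the second-order scattering contrast.
#'
#' @param ratio_mn `shi_ratio` at a non-fundamental label.
#' @param sample00,ref00 The `(0,0)` `shi_harmonic` of the sample and the
#'   reference (needed for the visibility normalization).
#' @return List with the real `map` and logical `valid`.
#' @export
scattering <- function(ratio_mn, sample00, ref00) {
  stopifnot(inherits(ratio_mn, "shi_ratio"),
            inherits(sample00, "shi_harmonic"), inherits(ref00, "shi_harmonic"))
  stop_if_label(ratio_mn, FALSE, "scattering")
  if (!all(sample00$label == 0L) || !all(ref00$label == 0L)) {
    stop("sample00 and ref00 must be the (0,0) harmonics", call. = FALSE)
  }
  r_mn <- Mod(ratio_mn$values)
  s00 <- Mod(sample00$values)
  r00 <- Mod(ref00$values)
  valid <- ratio_mn$valid & r_mn > 0 & s00 > 0 & r00 > 0
  out <- matrix(0, nrow(r_mn), ncol(r_mn))
  # -ln[(|S_mn|/|S_00|)/(|R_mn|/|R_00|)] = -ln|S_mn/R_mn| + ln(|S_00|/|R_00|)
  out[valid] <- -log(r_mn[valid]) + log(s00[valid] / r00[valid])
  list(map = out, valid = valid)
}

#' Differential phase contrast of a first or second order harmonic
#'
#' `P = arg(I^S_mn / I^R_mn)`, the principal-value phase in `(-pi, pi]`,
#' proportional to the lateral beamlet displacement along the harmonic
#' direction: a rigid pattern shift of `delta` pixels along +x appears as
#' `P = 2 pi delta / d` in the `(+1, 0)` harmonic. The fundamental
#' harmonic carries no phase (its label is rejected).
#'
#' @param ratio_mn `shi_ratio` at a non-fundamental label.
#' @return List with the real `map` in radians and logical `valid`.
#' @export
dpc <- function(ratio_mn) {
  stopifnot(inherits(ratio_mn, "shi_ratio"))
  stop_if_label(ratio_mn, FALSE, "differential phase")
  out <- Arg(ratio_mn$values)
  out[!ratio_mn$valid] <- 0
  list(map = out, valid = ratio_mn$valid)
}

#' Average horizontal and vertical contrast directions
#'
#' The mask is periodic along both axes, so each first-order contrast
#' exists in a horizontal and a vertical flavor; the bidirectional map is
#' their pixel-wise arithmetic mean.
#'
#' @param map_h,map_v Real maps of identical shape.
#' @return Real matrix.
#' @export
combine_directions <- function(map_h, map_v) {
  if (!identical(dim(map_h), dim(map_v))) {
    stop("direction maps must share one shape", call. = FALSE)
  }
  (map_h + map_v) / 2
}

# --- phase unwrapping ------------------------------------------------------

.unwrap_registry <- new.env(parent = emptyenv())

unwrap_none <- function(p) p

# Row-by-row 1-D unwrapping (Itoh's method via signal::unwrap), with the
# first column unwrapped first to tie the rows together.
unwrap_itoh <- function(p) {
  first_col <- signal::unwrap(p[, 1])
  out <- t(apply(p, 1, signal::unwrap))
  out <- out - out[, 1] + first_col
  out
}

wrap_to_pi <- function(x) x - 2 * pi * round(x / (2 * pi))

# Quality-guided flood fill: pixels are integrated into the unwrapped
# region in order of a local smoothness quality (negative wrapped-phase
# gradient energy), so noisy pixels are visited last and cannot seed
# error propagation into clean regions.
unwrap_quality <- function(p) {
  n1 <- nrow(p); n2 <- ncol(p)
  gx <- matrix(0, n1, n2); gy <- matrix(0, n1, n2)
  gx[, -n2] <- wrap_to_pi(p[, -1] - p[, -n2])
  gy[-n1, ] <- wrap_to_pi(p[-1, ] - p[-n1, ])
  quality <- -(abs(gx) + abs(gy) +
                 abs(cbind(0, gx[, -n2])) + abs(rbind(0, gy[-n1, ])))
  out <- p
  done <- matrix(FALSE, n1, n2)
  inq <- matrix(FALSE, n1, n2)
  qval <- rep(-Inf, n1 * n2)
  seed <- which.max(quality)
  done[seed] <- TRUE
  neighbors <- function(i) {
    r <- ((i - 1) %% n1) + 1; c <- ((i - 1) %/% n1) + 1
    nb <- integer(0)
    if (r > 1) nb <- c(nb, i - 1)
    if (r < n1) nb <- c(nb, i + 1)
    if (c > 1) nb <- c(nb, i - n1)
    if (c < n2) nb <- c(nb, i + n1)
    nb
  }
  push <- function(i) {
    fresh <- i[!done[i] & !inq[i]]
    inq[fresh] <<- TRUE
    qval[fresh] <<- quality[fresh]
  }
  push(neighbors(seed))
  repeat {
    i <- which.max(qval)
    if (!is.finite(qval[i])) break
    qval[i] <- -Inf; inq[i] <- FALSE
    nb <- neighbors(i)
    ref <- nb[done[nb]]
    ref <- ref[which.max(quality[ref])]
    out[i] <- out[ref] + wrap_to_pi(p[i] - p[ref])
    done[i] <- TRUE
    push(nb)
  }
  out
}

.unwrap_registry$none <- unwrap_none
.unwrap_registry$itoh <- unwrap_itoh
.unwrap_registry$quality <- unwrap_quality

#' Unwrap a differential-phase map
#'
#' Phase values are only known modulo 2 pi; strongly refracting samples
#' can wrap. Every method returns a map congruent to the input modulo
#' 2 pi pixel-wise. Shipped methods: `"none"` (identity), `"itoh"`
#' (row-wise 1-D cumulative unwrapping) and `"quality"` (quality-guided
#' 2-D region growing). Further algorithms can be plugged in with
#' [register_unwrap_method()].
#'
#' @param p Real phase map in radians.
#' @param method Method name.
#' @return Unwrapped map.
#' @export
unwrap <- function(p, method = "none") {
  fn <- get0(method, envir = .unwrap_registry, inherits = FALSE)
  if (is.null(fn)) {
    stop("unknown unwrap method '", method, "'; available: ",
         paste(sort(ls(.unwrap_registry)), collapse = ", "), call. = FALSE)
  }
  fn(p)
}

#' @rdname unwrap
#' @param name Registry name for the new method.
#' @param fn Function taking and returning a phase matrix; must preserve
#'   values modulo 2 pi.
#' @export
register_unwrap_method <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  assign(name, fn, envir = .unwrap_registry)
  invisible(name)
}
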