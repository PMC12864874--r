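#' Rebin a divergent-beam projection onto a parallel-beam grid
#'
#' For small divergence angles, a flat-detector projection acquired in a
#' point-source geometry can be remapped to the equivalent parallel-beam
#' projection: a detector coordinate `(u, v)` measured from the principal
#' ray corresponds to the parallel-ray coordinate
#' \deqn{t = u d2 / \sqrt{dsd^2 + u^2 + v^2}}
#' (and likewise for `v`), expressed on the sample-plane grid whose pitch
#' is [sample_plane_pixel_size()]. The remap is inverted in closed form
#' and resampled with bilinear interpolation; the output has the input's
#' shape, and in the limit `dsd -> infinity` the map is the identity. A
#' `rebinned` attribute records provenance so the (lossy) remap cannot be
#' applied twice by accident.
#'
#' @param projection Real matrix (detector rows x cols).
#' @param geom A [geometry()].
#' @return Rebinned matrix of the same shape, with attribute
#'   `rebinned = TRUE`.
#' @export
rebin_cone_to_parallel <- function(projection, geom) {
  stopifnot(is.matrix(projection), all(is.finite(projection)),
            inherits(geom, "shi_geometry"))
  if (isTRUE(attr(projection, "rebinned"))) {
    stop("projection has already been rebinned", call. = FALSE)
  }
  n1 <- nrow(projection); n2 <- ncol(projection)
  p_cm <- geom$pixel_um * 1e-4
  ps_cm <- p_cm * geom$d2 / geom$dsd      # sample-plane pitch
  cv <- (n1 + 1) / 2; cu <- (n2 + 1) / 2  # principal ray at array center
  # output grid in parallel coordinates (t horizontal, s vertical)
  t <- (seq_len(n2) - cu) * ps_cm
  s <- (seq_len(n1) - cv) * ps_cm
  TT <- matrix(t, n1, n2, byrow = TRUE)
  SS <- matrix(s, n1, n2)
  r2 <- TT^2 + SS^2
  # closed-form inverse of t = u d2 / sqrt(dsd^2 + u^2 + v^2)
  rho2 <- r2 * geom$dsd^2 / pmax(geom$d2^2 - r2, .Machine$double.eps)
  R <- sqrt(geom$dsd^2 + rho2)
  U <- TT * R / geom$d2
  V <- SS * R / geom$d2
  out <- matrix(
    bilinear_interp(projection, as.vector(V / p_cm + cv),
                    as.vector(U / p_cm + cu), clamp = TRUE),
    n1, n2)
  attr(out, "rebinned") <- TRUE
  out
}

#' Sinogram container
#'
#' @param values Matrix (angle x detector column) for one slice, or a
#'   3-D array (angle x row x column).
#' @param angles_deg Strictly increasing angles in `[0, 180)`, length
#'   equal to the first dimension of `values`, at least 2.
#' @param label Harmonic label `c(m, n)` the contrast derives from.
#' @param kind Contrast kind string.
#' @return An object of class `shi_sinogram`.
#' @export
sinogram <- function(values, angles_deg, label = c(0L, 0L), kind = "absorption") {
  stopifnot(is.numeric(values), length(dim(values)) %in% c(2L, 3L))
  if (length(angles_deg) < 2L) stop("a sinogram needs at least 2 angles", call. = FALSE)
  if (any(diff(angles_deg) <= 0)) stop("angles must be strictly increasing", call. = FALSE)
  if (any(angles_deg < 0) || any(angles_deg >= 180)) {
    stop("angles must lie in [0, 180)", call. = FALSE)
  }
  if (dim(values)[1] != length(angles_deg)) {
    stop("first dimension of values must match the angle count", call. = FALSE)
  }
  structure(list(values = values, angles_deg = as.numeric(angles_deg),
                 label = as.integer(label), kind = kind),
            class = "shi_sinogram")
}

#' @export
print.shi_sinogram <- function(x, ...) {
  cat(sprintf("<shi_sinogram> %s (%+d,%+d): %d angles x %s\n", x$kind,
              x$label[1], x$label[2], dim(x$values)[1],
              paste(dim(x$values)[-1], collapse = " x ")))
  invisible(x)
}

#' Assemble a per-harmonic contrast sinogram from a CT project
#'
#' Reads the per-angle contrast images written under
#' `out/harmonic_{label}/{kind}/angle_*.tif` (see [ct_output_path()]),
#' sorted by encoded angle index, and stacks them into a sinogram.
#' Missing or differently shaped angle files raise an error naming the
#' angle.
#'
#' @param project A `shi_project` in `"ct"` mode.
#' @param label Harmonic label `c(m, n)`.
#' @param kind Contrast kind (`"absorption"`, `"dpc"`, `"scattering"`).
#' @param angles_deg Optional angle vector; defaults to the project's
#'   `angles.yml` (written by [simulate_ct()]) or, failing that, an even
#'   spacing of `[0, 180)` over the files found.
#' @return A `shi_sinogram` with 3-D values (angle x row x col).
#' @export
assemble_sinogram <- function(project, label, kind = "absorption",
                              angles_deg = NULL) {
  stopifnot(inherits(project, "shi_project"))
  dir <- dirname(ct_output_path(project, 1L, label, kind))
  if (!dir.exists(dir)) stop("no contrast directory: ", dir, call. = FALSE)
  files <- list.files(dir, pattern = "^angle_\\d{5}\\.tif$", full.names = TRUE)
  if (length(files) == 0L) stop("no angle files in ", dir, call. = FALSE)
  idx <- as.integer(sub("^angle_(\\d{5})\\.tif$", "\\1", basename(files)))
  files <- files[order(idx)]
  idx <- sort(idx)
  if (!identical(idx, seq_len(max(idx)))) {
    missing <- setdiff(seq_len(max(idx)), idx)
    stop("missing angle file(s) for index: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(angles_deg)) {
    ay <- file.path(project$root, "angles.yml")
    angles_deg <- if (file.exists(ay)) unlist(yaml::read_yaml(ay)$angles_deg)
                  else (idx - 1L) * 180 / length(idx)
  }
  first <- read_image(files[1])
  vals <- array(NA_real_, c(length(files), nrow(first), ncol(first)))
  for (i in seq_along(files)) {
    img <- read_image(files[i])
    if (!identical(dim(img), dim(first))) {
      stop("shape mismatch at angle index ", idx[i], call. = FALSE)
    }
    vals[i, , ] <- img
  }
  sinogram(vals, angles_deg, label = label, kind = kind)
}

ramlak_filter_projections <- function(p) {
  # p: angles x detector. Zero-padded frequency-domain ramp filtering.
  nd <- ncol(p)
  m <- 2^ceiling(log2(2 * nd))
  f <- c(0:(m / 2), -(m / 2 - 1):-1) / m
  ramp <- 2 * abs(f)
  pad <- matrix(0, nrow(p), m)
  pad[, seq_len(nd)] <- p
  ft <- t(apply(pad, 1, stats::fft))
  filt <- t(apply(ft * rep(ramp, each = nrow(p)), 1,
                  function(r) Re(stats::fft(r, inverse = TRUE)) / m))
  filt[, seq_len(nd), drop = FALSE]
}

#' Parallel-beam filtered backprojection of one sinogram slice
#'
#' Classical FBP: each projection is ramp-filtered (Ram-Lak, ideal
#' `|f|` response on the zero-padded detector axis) and smeared back
#' across the image grid along its ray direction, with linear
#' interpolation on the detector and the standard `pi / (2 N_angles)`
#' normalization. The operation is linear in the sinogram. Only the
#' rotation center must be supplied as a geometric parameter.
#'
#' @param sino A `shi_sinogram` with 2-D values (angle x detector), or a
#'   plain matrix plus `angles_deg`.
#' @param center Rotation center as a 1-based detector column coordinate;
#'   defaults to the detector midpoint.
#' @param filter Reconstruction filter; only `"ramlak"` is provided.
#' @param angles_deg Angles when `sino` is a plain matrix.
#' @return Square slice matrix of side equal to the detector width.
#' @export
fbp_reconstruct <- function(sino, center = NULL, filter = "ramlak",
                            angles_deg = NULL) {
  filter <- match.arg(filter, "ramlak")
  if (inherits(sino, "shi_sinogram")) {
    stopifnot(length(dim(sino$values)) == 2L)
    p <- sino$values
    angles_deg <- sino$angles_deg
  } else {
    p <- sino
    if (is.null(angles_deg)) stop("angles_deg required for a plain matrix", call. = FALSE)
  }
  nd <- ncol(p)
  if (is.null(center)) center <- (nd + 1) / 2
  if (center < 1 || center > nd) {
    stop("rotation center ", center, " lies outside the detector [1, ", nd, "]",
         call. = FALSE)
  }
  q <- ramlak_filter_projections(p)
  xs <- seq_len(nd) - center
  X <- matrix(xs, nd, nd, byrow = TRUE)
  Y <- matrix(xs, nd, nd)
  recon <- matrix(0, nd, nd)
  for (a in seq_along(angles_deg)) {
    th <- angles_deg[a] * pi / 180
    tq <- X * cos(th) + Y * sin(th) + center
    prof <- stats::approx(seq_len(nd), q[a, ], xout = as.vector(tq),
                          yleft = 0, yright = 0)$y
    recon <- recon + matrix(prof, nd, nd)
  }
  recon * pi / (2 * length(angles_deg))
}

#' Parallel projection (radon transform) of an image
#'
#' Line integrals of `img` along rays at each angle; the detector
#' coordinate of pixel `(x, y)` (centered) at angle `theta` is
#' `t = x cos(theta) + y sin(theta)`. Used by the simulator and as the
#' forward model matching [fbp_reconstruct()].
#'
#' @param img Square-ish numeric matrix.
#' @param angles_deg Angle vector in degrees.
#' @return Matrix (angle x detector column), detector width = `ncol(img)`.
#' @export
radon_transform <- function(img, angles_deg) {
  n1 <- nrow(img); n2 <- ncol(img)
  cy <- (n1 + 1) / 2; cx <- (n2 + 1) / 2
  t <- seq_len(n2) - cx
  s <- seq_len(n1) - cy
  out <- matrix(0, length(angles_deg), n2)
  for (a in seq_along(angles_deg)) {
    th <- angles_deg[a] * pi / 180
    # sample along each ray: position = t * (cos, sin) + s * (-sin, cos)
    Xq <- outer(-s * sin(th), t * cos(th), `+`) + cx
    Yq <- outer(s * cos(th), t * sin(th), `+`) + cy
    vals <- bilinear_interp(img, as.vector(Yq), as.vector(Xq))
    out[a, ] <- colSums(matrix(vals, n1, n2))
  }
  out
}

entropy_nats <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Reconstruction quality metrics
#'
#' Compares a reconstruction (or any image) against a reference of the
#' same shape with the four standard measures:
#' * NRMSE: root-mean-square error divided by the reference data range;
#' * PSNR: `10 log10(range^2 / MSE)` in dB (`Inf` for identical input);
#' * MSSIM: mean local structural similarity over 7 x 7 windows with the
#'   standard stabilizing constants `(0.01 L)^2`, `(0.03 L)^2` on the
#'   reference range `L`;
#' * NMI: normalized mutual information `(H(X) + H(Y)) / H(X, Y)` from a
#'   256-bin joint histogram, in `[1, 2]` (2 for identical images).
#'
#' @param recon,reference Numeric matrices (or 3-D arrays, compared
#'   slice-wise and averaged) of identical shape; the reference must not
#'   be constant.
#' @return An object of class `shi_metrics`: list with `nrmse`, `psnr_db`,
#'   `mssim`, `nmi`.
#' @export
quality_metrics <- function(recon, reference) {
  if (!identical(dim(recon), dim(reference))) {
    stop("recon and reference must share one shape", call. = FALSE)
  }
  if (length(dim(recon)) == 3L) {
    per <- lapply(seq_len(dim(recon)[1]), function(i) {
      quality_metrics(recon[i, , ], reference[i, , ])
    })
    return(structure(list(
      nrmse = mean(vapply(per, `[[`, 0, "nrmse")),
      psnr_db = mean(vapply(per, `[[`, 0, "psnr_db")),
      mssim = mean(vapply(per, `[[`, 0, "mssim")),
      nmi = mean(vapply(per, `[[`, 0, "nmi"))), class = "shi_metrics"))
  }
  rng <- max(reference) - min(reference)
  if (rng <= 0) stop("reference image is constant; metrics undefined", call. = FALSE)
  mse <- mean((recon - reference)^2)
  nrmse <- sqrt(mse) / rng
  psnr <- if (mse == 0) Inf else 10 * log10(rng^2 / mse)

  k <- 7L
  c1 <- (0.01 * rng)^2; c2 <- (0.03 * rng)^2
  mx <- box_mean_valid(recon, k);  my <- box_mean_valid(reference, k)
  mxx <- box_mean_valid(recon^2, k); myy <- box_mean_valid(reference^2, k)
  mxy <- box_mean_valid(recon * reference, k)
  vx <- mxx - mx^2; vy <- myy - my^2; cxy <- mxy - mx * my
  ssim <- ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
  mssim <- mean(ssim)

  nb <- 256L
  bin <- function(x) {
    r <- range(x)
    if (r[2] == r[1]) rep(1L, length(x))
    else pmin(nb, 1L + floor((x - r[1]) / (r[2] - r[1]) * nb))
  }
  ix <- bin(as.vector(recon)); iy <- bin(as.vector(reference))
  joint <- tabulate((ix - 1L) * nb + iy, nbins = nb * nb)
  hx <- entropy_nats(tabulate(ix, nb))
  hy <- entropy_nats(tabulate(iy, nb))
  hxy <- entropy_nats(joint)
  nmi <- (hx + hy) / hxy

  structure(list(nrmse = nrmse, psnr_db = psnr, mssim = mssim, nmi = nmi),
            class = "shi_metrics")
}

#' @export
print.shi_metrics <- function(x, ...) {
  cat(sprintf("<shi_metrics> NRMSE %.4g  PSNR %.2f dB  MSSIM %.4f  NMI %.4f\n",
              x$nrmse, x$psnr_db, x$mssim, x$nmi))
  invisible(x)
}

#' Reconstruction quality versus projection count
#'
#' For each requested count `N`, keeps an evenly spaced angle subset
#' (always including the first angle), reconstructs the slice with
#' [fbp_reconstruct()], and scores it against the full-count
#' reconstruction with [quality_metrics()]. Fewer projections give
#' noisier streakier slices, so NRMSE falls and PSNR/MSSIM/NMI rise as
#' `N` grows.
#'
#' @param full_sino A 2-D `shi_sinogram` (angle x detector).
#' @param counts Integer vector of projection counts, each at most the
#'   available angle count; results are keyed by `N` regardless of input
#'   order.
#' @param center Rotation center passed to [fbp_reconstruct()].
#' @return Data frame with columns `n`, `nrmse`, `psnr_db`, `mssim`,
#'   `nmi`, sorted by `n`.
#' @export
projection_count_study <- function(full_sino, counts, center = NULL) {
  stopifnot(inherits(full_sino, "shi_sinogram"), length(dim(full_sino$values)) == 2L)
  n_avail <- length(full_sino$angles_deg)
  counts <- sort(unique(as.integer(counts)))
  if (any(counts < 2L) || any(counts > n_avail)) {
    stop("counts must lie in [2, ", n_avail, "]", call. = FALSE)
  }
  reference <- fbp_reconstruct(full_sino, center = center)
  rows <- lapply(counts, function(n) {
    idx <- unique(1L + floor((seq_len(n) - 1L) * n_avail / n))
    sub <- sinogram(full_sino$values[idx, , drop = FALSE],
                    full_sino$angles_deg[idx],
                    label = full_sino$label, kind = full_sino$kind)
    m <- quality_metrics(fbp_reconstruct(sub, center = center), reference)
    data.frame(n = n, nrmse = m$nrmse, psnr_db = m$psnr_db,
               mssim = m$mssim, nmi = m$nmi)
  })
  do.call(rbind, rows)
}
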