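#' Synthetic mask specification
#'
#' Describes the projected intensity pattern of an inverted Hartmann
#' mask: a regular array of absorbing pillars on a transparent substrate,
#' modeled as the separable product of two square waves. `period` is the
#' projected period in detector pixels and must satisfy the Nyquist
#' constraint `period >= 3`.
#'
#' @param period Projected period in detector pixels (real, >= 3).
#' @param duty Fraction of each period occupied by pillar, in (0, 1).
#' @param transmission Pillar transmission in `[0, 1)`.
#' @param offset Lateral pattern offset `c(x, y)` in pixels.
#' @param edge_sigma Gaussian softness of the pillar edges in pixels,
#'   emulating the penumbral blur of a finite focal spot; 0 gives hard
#'   edges. Evaluated analytically, so the rendered pattern stays smooth,
#'   non-negative and exactly periodic.
#' @return An object of class `shi_mask`.
#' @export
mask_spec <- function(period, duty = 0.5, transmission = 0, offset = c(0, 0),
                      edge_sigma = 0.5) {
  if (!is.finite(period) || period < 3) {
    stop(sprintf(
      "Nyquist violation: projected period %.3f px is below the minimum of 3 detector pixels",
      period), call. = FALSE)
  }
  stopifnot(duty > 0, duty < 1, transmission >= 0, transmission < 1,
            length(offset) == 2L, edge_sigma >= 0)
  structure(list(period = period, duty = duty, transmission = transmission,
                 offset = as.numeric(offset), edge_sigma = edge_sigma),
            class = "shi_mask")
}

# One axis of the pillar pattern: `transmission` over the pillar fraction
# of each period, 1 between pillars. With edge_sigma > 0 the hard profile
# is convolved with a Gaussian in closed form (sum of error functions over
# neighboring periods), which keeps the mean per period exact.
square_wave <- function(u, period, duty, transmission, edge_sigma = 0) {
  phase <- (u / period) %% 1
  if (edge_sigma == 0) return(ifelse(phase < duty, transmission, 1))
  x <- phase * period
  open_frac <- 0
  for (k in -3:3) {
    open_frac <- open_frac +
      stats::pnorm((x - (duty + k) * period) / edge_sigma) -
      stats::pnorm((x - (1 + k) * period) / edge_sigma)
  }
  transmission + (1 - transmission) * open_frac
}

#' Render the mask transmission pattern
#'
#' Evaluates the separable pillar pattern analytically at every pixel
#' (optionally at locally displaced coordinates, which is how refraction
#' is emulated), so sub-pixel pattern shifts are exact rather than
#' interpolated. Along each axis the wave takes the value
#' `transmission` over a `duty` fraction of the period and 1 elsewhere,
#' so the per-axis mean over a full period is
#' `(1 - duty) + duty * transmission`.
#'
#' @param mask A [mask_spec()].
#' @param shape `c(rows, cols)`.
#' @param shift_x,shift_y Scalar or matrix beamlet displacement fields in
#'   pixels; a positive value displaces the pattern toward +x / +y.
#' @return Numeric matrix in `[transmission^2, 1]`.
#' @export
render_mask <- function(mask, shape, shift_x = 0, shift_y = 0) {
  stopifnot(inherits(mask, "shi_mask"), length(shape) == 2L)
  X <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  Y <- matrix(seq_len(shape[1]), shape[1], shape[2])
  square_wave(X - mask$offset[1] - shift_x, mask$period, mask$duty,
              mask$transmission, mask$edge_sigma) *
    square_wave(Y - mask$offset[2] - shift_y, mask$period, mask$duty,
                mask$transmission, mask$edge_sigma)
}

broadcast_map <- function(x, shape, name) {
  if (is.matrix(x)) {
    if (!identical(dim(x), as.integer(shape))) {
      stop(name, " map shape does not match the frame shape", call. = FALSE)
    }
    x
  } else matrix(x, shape[1], shape[2])
}

#' Ground-truth phantom maps for the simulator
#'
#' Per-pixel ground truth the forward model consumes and parameter
#' recovery tests compare against: optical thickness `mu_d`
#' (dimensionless, Beer-Lambert exponent), beamlet displacement fields
#' `shift_x`/`shift_y` at the detector (pixels; the refraction proxy read
#' out by the differential phase), and the Gaussian scatter-blur width
#' `sigma` (pixels; the diffusion proxy read out by the visibility loss).
#'
#' @param shape `c(rows, cols)`.
#' @param mu_d,shift_x,shift_y,sigma Scalars or matrices of shape `shape`;
#'   `mu_d >= 0`, `sigma >= 0`.
#' @return An object of class `shi_phantom`.
#' @export
phantom_spec <- function(shape, mu_d = 0, shift_x = 0, shift_y = 0, sigma = 0) {
  ph <- list(mu_d = broadcast_map(mu_d, shape, "mu_d"),
             shift_x = broadcast_map(shift_x, shape, "shift_x"),
             shift_y = broadcast_map(shift_y, shape, "shift_y"),
             sigma = broadcast_map(sigma, shape, "sigma"))
  if (min(ph$mu_d) < 0) stop("mu_d must be non-negative", call. = FALSE)
  if (min(ph$sigma) < 0) stop("sigma must be non-negative", call. = FALSE)
  structure(c(ph, list(shape = as.integer(shape))), class = "shi_phantom")
}

#' @rdname phantom_spec
#' @param center_frac,radius_frac Disk center and radius as fractions of
#'   the frame extent.
#' @param ... Passed to [phantom_spec()]; scalar values apply inside the
#'   disk, zero outside.
#' @export
phantom_disk <- function(shape, center_frac = c(0.5, 0.5), radius_frac = 0.25, ...) {
  inside <- disk_mask(shape, center_frac, radius_frac)
  args <- list(...)
  maps <- lapply(args, function(v) {
    m <- matrix(0, shape[1], shape[2]); m[inside] <- v; m
  })
  do.call(phantom_spec, c(list(shape = shape), maps))
}

#' @rdname phantom_spec
#' @return `disk_mask()` returns the logical inside-the-disk matrix used
#'   by `phantom_disk()`; handy for selecting region interiors when
#'   comparing retrieved maps against ground truth.
#' @export
disk_mask <- function(shape, center_frac = c(0.5, 0.5), radius_frac = 0.25) {
  Y <- matrix(seq_len(shape[1]), shape[1], shape[2])
  X <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  cy <- center_frac[1] * shape[1]; cx <- center_frac[2] * shape[2]
  r <- radius_frac * min(shape)
  (Y - cy)^2 + (X - cx)^2 <= r^2
}

#' Simulation configuration
#'
#' Detector and illumination model shared by all frame categories:
#' expected photon counts `photons * transmission * gain`, a fixed-pattern
#' dark offset, Poisson shot noise and Gaussian read noise. With a fixed
#' seed the rendered frames are reproducible bit for bit. The default
#' gain map is a gentle parabolic vignette so flat-field correction has
#' real structure to remove.
#'
#' @param shape Frame shape, default 512 x 512.
#' @param photons Expected photon count at bright level (Poisson scale).
#' @param gain Scalar, matrix, or `"vignette"` (default) for the built-in
#'   smooth gain map.
#' @param dark_offset,dark_spread Mean and fixed-pattern spread of the
#'   dark level (ADU).
#' @param read_sd Gaussian read-noise standard deviation (ADU).
#' @param shot_noise Logical; disable for noiseless forward runs.
#' @param repeats Frames per category.
#' @param seed RNG seed.
#' @return An object of class `shi_simconfig`.
#' @export
sim_config <- function(shape = c(512L, 512L), photons = 1e4, gain = "vignette",
                       dark_offset = 100, dark_spread = 2, read_sd = 2,
                       shot_noise = TRUE, repeats = 1L, seed = 1L) {
  stopifnot(photons > 0, repeats >= 1L)
  shape <- as.integer(shape)
  if (identical(gain, "vignette")) {
    Y <- matrix(seq_len(shape[1]) / shape[1] - 0.5, shape[1], shape[2])
    X <- matrix(seq_len(shape[2]) / shape[2] - 0.5, shape[1], shape[2], byrow = TRUE)
    gain <- 1 - 0.15 * (X^2 + Y^2) / 0.5
  } else gain <- broadcast_map(gain, shape, "gain")
  structure(list(shape = shape, photons = photons, gain = gain,
                 dark_offset = dark_offset, dark_spread = dark_spread,
                 read_sd = read_sd, shot_noise = isTRUE(shot_noise),
                 repeats = as.integer(repeats), seed = as.integer(seed)),
            class = "shi_simconfig")
}

# Piecewise-constant spatially varying Gaussian blur: one FFT blur per
# distinct sigma value present in the map, composited per region.
blur_piecewise <- function(img, sigma_map) {
  sigmas <- sort(unique(as.vector(sigma_map)))
  out <- img
  for (s in sigmas[sigmas > 0]) {
    sel <- sigma_map == s
    blurred <- gaussian_blur_fft(img, s)
    out[sel] <- blurred[sel]
  }
  out
}

detector_counts <- function(transmission, cfg, offset_map) {
  expected <- cfg$photons * transmission * cfg$gain
  counts <- if (cfg$shot_noise) {
    matrix(stats::rpois(length(expected), as.vector(expected)),
           nrow(expected), ncol(expected))
  } else expected
  if (cfg$read_sd > 0) {
    counts <- counts + matrix(stats::rnorm(length(counts), sd = cfg$read_sd),
                              nrow(counts), ncol(counts))
  }
  pmax(counts + offset_map, 0)
}

#' Render synthetic dark, bright, reference and sample frame stacks
#'
#' Forward model of one measurement. Sample image formation order:
#' the mask pattern is (1) evaluated at locally displaced coordinates
#' (refraction), (2) attenuated by `exp(-mu_d)` (Beer-Lambert), (3)
#' blurred by the per-region Gaussian scatter kernel (visibility loss),
#' then (4) passed through the shared detector model (gain, dark offset,
#' shot and read noise). Dark frames see no beam, bright frames see the
#' unmodulated beam, reference frames see the undisturbed mask.
#'
#' @param mask A [mask_spec()].
#' @param phantom A [phantom_spec()], or `NULL` to render only the three
#'   sample-free categories.
#' @param cfg A [sim_config()].
#' @return Named list of [frame_stack()]s (`dark`, `bright`, `reference`,
#'   and `sample` when a phantom is given).
#' @export
render_frames <- function(mask, phantom = NULL, cfg = sim_config()) {
  stopifnot(inherits(mask, "shi_mask"), inherits(cfg, "shi_simconfig"))
  shape <- cfg$shape
  if (!is.null(phantom)) {
    stopifnot(inherits(phantom, "shi_phantom"))
    if (!identical(phantom$shape, shape)) {
      stop("phantom shape does not match the configured frame shape", call. = FALSE)
    }
    if (max(abs(phantom$shift_x)) >= mask$period / 2 ||
        max(abs(phantom$shift_y)) >= mask$period / 2) {
      stop("beamlet displacement must stay below half the mask period",
           call. = FALSE)
    }
  }
  t_ref <- render_mask(mask, shape)
  t_sample <- if (!is.null(phantom)) {
    warped <- render_mask(mask, shape,
                          shift_x = phantom$shift_x, shift_y = phantom$shift_y)
    blur_piecewise(warped * exp(-phantom$mu_d), phantom$sigma)
  }
  with_seed(cfg$seed, {
    offset_map <- cfg$dark_offset +
      if (cfg$dark_spread > 0) {
        matrix(stats::rnorm(prod(shape), sd = cfg$dark_spread), shape[1], shape[2])
      } else 0
    mk_stack <- function(transmission, category) {
      frame_stack(lapply(seq_len(cfg$repeats), function(i) {
        frame(detector_counts(transmission, cfg, offset_map),
              category = category, index = i)
      }))
    }
    out <- list(dark = mk_stack(0, "dark"),
                bright = mk_stack(1, "bright"),
                reference = mk_stack(t_ref, "reference"))
    if (!is.null(t_sample)) out$sample <- mk_stack(t_sample, "sample")
    out
  })
}

#' Three-dimensional phantom volume for CT simulation
#'
#' @param mu 3-D array `[y, x, z]` of attenuation per voxel (so its line
#'   integral is the projected optical thickness).
#' @param sigma2 Optional 3-D array of scatter variance density per voxel
#'   (line-integrated and square-rooted to a projected blur width).
#' @return An object of class `shi_phantom3d`.
#' @export
phantom_volume <- function(mu, sigma2 = NULL) {
  stopifnot(length(dim(mu)) == 3L, all(is.finite(mu)), min(mu) >= 0)
  if (!is.null(sigma2)) {
    stopifnot(identical(dim(sigma2), dim(mu)), min(sigma2) >= 0)
  }
  structure(list(mu = mu, sigma2 = sigma2, dim = dim(mu)),
            class = "shi_phantom3d")
}

#' @rdname phantom_volume
#' @param n Cube side in voxels.
#' @param center_frac Center `c(y, x, z)` as fractions of the cube.
#' @param radius_frac Radius as fraction of `n` (cylinder axis along z
#'   when `height_frac` is given, else a sphere).
#' @param value Attenuation per voxel inside the body.
#' @param height_frac Optional cylinder height fraction.
#' @export
phantom_cylinder <- function(n, center_frac = c(0.5, 0.5, 0.5),
                             radius_frac = 0.3, value = 0.01,
                             height_frac = 0.6) {
  idx <- seq_len(n)
  Y <- array(idx, c(n, n, n))
  X <- aperm(Y, c(2, 1, 3))
  Z <- aperm(Y, c(3, 2, 1))
  cy <- center_frac[1] * n; cx <- center_frac[2] * n; cz <- center_frac[3] * n
  r <- radius_frac * n
  body <- (Y - cy)^2 + (X - cx)^2 <= r^2 & abs(Z - cz) <= height_frac * n / 2
  mu <- array(0, c(n, n, n)); mu[body] <- value
  phantom_volume(mu)
}

#' Simulate a full CT scan to disk
#'
#' For each of `n_angles` evenly spaced angles in `[0, 180)` the phantom
#' volume is line-integrated along parallel rays at the sample plane
#' (slice-wise radon transform), giving per-angle projected `mu_d` (and
#' optional scatter width) maps; frames are then rendered with
#' [render_frames()] and written into a CT [init_project()] layout. The
#' mask-only reference, dark and bright stacks are rendered once and
#' shared by all angles, as in a real scan. Ground-truth projected maps
#' go to `ground_truth/`; the angle list to `angles.yml`. Deterministic
#' for a fixed config seed.
#'
#' @param phantom3d A [phantom_volume()]; frame shape must equal
#'   `c(nz, nx)` of the volume.
#' @param n_angles Number of projections (>= 2).
#' @param mask A [mask_spec()].
#' @param cfg A [sim_config()] with `shape = c(dim(mu)[3], dim(mu)[2])`.
#' @param root Project root directory.
#' @return The `shi_project`, invisibly.
#' @export
simulate_ct <- function(phantom3d, n_angles, mask, cfg, root) {
  stopifnot(inherits(phantom3d, "shi_phantom3d"), n_angles >= 2L)
  d3 <- phantom3d$dim
  if (!identical(cfg$shape, as.integer(c(d3[3], d3[2])))) {
    stop("frame shape must be c(nz, nx) = ", d3[3], " x ", d3[2], call. = FALSE)
  }
  project <- init_project(root, "ct")
  angles <- (seq_len(n_angles) - 1L) * 180 / n_angles
  yaml::write_yaml(list(n_angles = n_angles, angles_deg = as.list(angles)),
                   file.path(project$root, "angles.yml"))

  base <- render_frames(mask, phantom = NULL, cfg = cfg)
  save_stack(base$dark, project$categories[["dark"]])
  save_stack(base$bright, project$categories[["bright"]])
  save_stack(base$reference, project$categories[["reference"]])

  for (i in seq_len(n_angles)) {
    mu_d <- matrix(0, d3[3], d3[2])
    sig <- matrix(0, d3[3], d3[2])
    for (z in seq_len(d3[3])) {
      mu_d[z, ] <- radon_transform(phantom3d$mu[, , z], angles[i])
      if (!is.null(phantom3d$sigma2)) {
        sig[z, ] <- sqrt(pmax(radon_transform(phantom3d$sigma2[, , z], angles[i]), 0))
      }
    }
    ph <- phantom_spec(cfg$shape, mu_d = mu_d, sigma = sig)
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i  # independent noise per angle, still seeded
    frames <- render_frames(mask, ph, cfg_i)
    save_stack(frames$sample,
               file.path(project$categories[["sample"]], sprintf("angle_%05d", i)))
    write_image(mu_d, file.path(project$root, "ground_truth",
                                sprintf("angle_%05d_mu_d.tif", i)), bits = 32L)
  }
  invisible(project)
}
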