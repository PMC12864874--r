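test_that("render_mask obeys the duty-cycle arithmetic", {
  expect_error(mask_spec(2.5), "Nyquist")
  # vanishing pillars: nearly uniform transmission
  thin <- render_mask(mask_spec(8, duty = 0.01), c(64, 64))
  expect_gt(mean(thin), 0.97)
  expect_true(all(thin <= 1 + 1e-12))

  # period 8, duty 0.5, opaque pillars: separable means multiply to 0.25
  pat <- render_mask(mask_spec(8, duty = 0.5, transmission = 0), c(64, 64))
  for (r0 in c(1, 9, 25)) {
    win <- pat[r0:(r0 + 7), r0:(r0 + 7)]
    expect_equal(mean(win), 0.25, tolerance = 1e-6)
  }
  expect_true(all(pat >= 0 & pat <= 1))
})

test_that("the rendered mesh spectrum matches the square-wave Fourier series", {
  N <- 128L; p <- 8L
  pat <- render_mask(mask_spec(p, duty = 0.5, transmission = 0, edge_sigma = 0),
                     c(N, N))
  # oracle: per-axis Fourier coefficients from one sampled period
  axis_wave <- ifelse(((0:(p - 1)) / p) < 0.5, 0, 1)
  ck <- fft(axis_wave) / p
  sp <- fft(pat)
  for (kx in 0:2) for (ky in 0:2) {
    pred <- ck[kx + 1] * ck[ky + 1] * N * N
    got <- sp[1 + ky * N / p, 1 + kx * N / p]
    expect_equal(Mod(got), Mod(pred), tolerance = 1e-8)
  }
})

test_that("phantom constructors validate their maps", {
  expect_error(phantom_spec(c(32L, 32L), mu_d = -1), "non-negative")
  expect_error(phantom_spec(c(32L, 32L), sigma = -0.1), "non-negative")
  ph <- phantom_disk(c(32L, 32L), mu_d = 0.5, sigma = 1)
  expect_true(all(ph$mu_d[!disk_mask(c(32L, 32L))] == 0))
  expect_true(all(ph$mu_d[disk_mask(c(32L, 32L), radius_frac = 0.2)] == 0.5))
  cfg <- noiseless_cfg(c(32L, 32L))
  big_shift <- phantom_spec(c(32L, 32L), shift_x = 5)
  expect_error(render_frames(mask_spec(8), big_shift, cfg),
               "below half the mask period")
})

test_that("a null phantom renders samples statistically identical to references", {
  cfg <- sim_config(shape = c(64L, 64L), photons = 5e3, seed = 123)
  fr <- render_frames(mask_spec(8), phantom_spec(c(64L, 64L)), cfg)
  d <- as.vector(fr$sample$frames[[1]]$pixels - fr$reference$frames[[1]]$pixels)
  expect_gt(t.test(d)$p.value, 0.01)
})

test_that("frame rendering is seeded-deterministic down to the written bytes", {
  cfg <- sim_config(shape = c(32L, 32L), photons = 2e3, seed = 77)
  ph <- phantom_disk(c(32L, 32L), mu_d = 0.3)
  a <- render_frames(mask_spec(8), ph, cfg)
  b <- render_frames(mask_spec(8), ph, cfg)
  expect_identical(a$sample$frames[[1]]$pixels, b$sample$frames[[1]]$pixels)
  expect_identical(a$dark$frames[[1]]$pixels, b$dark$frames[[1]]$pixels)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  save_stack(a$sample, d1); save_stack(b$sample, d2)
  h1 <- unname(tools::md5sum(list.files(d1, full.names = TRUE)))
  h2 <- unname(tools::md5sum(list.files(d2, full.names = TRUE)))
  expect_identical(h1, h2)

  cfg2 <- cfg; cfg2$seed <- 78L
  c3 <- render_frames(mask_spec(8), ph, cfg2)
  expect_false(identical(a$sample$frames[[1]]$pixels, c3$sample$frames[[1]]$pixels))
})

test_that("bright-frame counts follow the configured energy budget", {
  cfg <- sim_config(shape = c(64L, 64L), photons = 8e3, gain = 1,
                    dark_offset = 120, dark_spread = 0, read_sd = 3, seed = 5)
  fr <- render_frames(mask_spec(8), NULL, cfg)
  counts <- fr$bright$frames[[1]]$pixels
  se <- sqrt(8e3 + 9) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - (8e3 + 120)), 3 * se)
})

test_that("noiseless recovery: absorption, phase and directional selectivity", {
  shape <- c(256L, 256L)
  cfg <- noiseless_cfg(shape)
  mask <- mask_spec(8)
  # pure absorber: A = mu d in the disk, S and P quiet
  pair <- corrected_pair(mask, phantom_disk(shape, mu_d = 0.7), cfg)
  cs <- retrieve_contrasts(pair$ref, pair$sample)
  w <- nrow(cs$absorption$map)
  interior <- disk_mask(c(w, w), c(0.5, 0.5), 0.25 * 0.75)
  expect_equal(mean(cs$absorption$map[interior]), 0.7, tolerance = 0.01)
  expect_lt(mean(abs(cs$bidirectional$S[interior])), 0.02)
  expect_lt(mean(abs(cs$bidirectional$P[interior])), 0.02)

  # rigid quarter-period shift along x: P(+1,0) = +pi/2, y harmonics silent
  pair2 <- corrected_pair(mask, phantom_spec(shape, shift_x = 2), cfg)
  cs2 <- retrieve_contrasts(pair2$ref, pair2$sample)
  expect_equal(mean(cs2$dpc[["+1+0"]]$map), pi / 2, tolerance = 1e-3)
  expect_equal(mean(cs2$dpc[["-1+0"]]$map), -pi / 2, tolerance = 1e-3)
  expect_lt(mean(abs(cs2$dpc[["+0+1"]]$map)),
            0.05 * mean(abs(cs2$dpc[["+1+0"]]$map)))

  # shift along y only: x harmonics silent, y harmonics respond. For a
  # fractional (sub-pixel) shift, sampling aliases of the high mask
  # harmonics fold onto the fundamental and limit the absolute phase
  # accuracy to a few mrad, hence the looser tolerance than the exact
  # integer-shift case above.
  pair3 <- corrected_pair(mask, phantom_spec(shape, shift_y = 1.1), cfg)
  cs3 <- retrieve_contrasts(pair3$ref, pair3$sample)
  expect_equal(mean(cs3$dpc[["+0+1"]]$map), 2 * pi * 1.1 / 8, tolerance = 5e-3)
  expect_lt(mean(abs(cs3$dpc[["+1+0"]]$map)),
            0.05 * mean(abs(cs3$dpc[["+0+1"]]$map)))
})

test_that("scattering strength grows monotonically with the diffuser width", {
  shape <- c(256L, 256L)
  cfg <- noiseless_cfg(shape)
  mask <- mask_spec(8)
  w <- NULL
  means <- vapply(c(0.4, 0.6, 0.8, 1.0, 1.2), function(s) {
    pair <- corrected_pair(mask, phantom_disk(shape, sigma = s), cfg)
    cs <- retrieve_contrasts(pair$ref, pair$sample)
    w <<- nrow(cs$bidirectional$S)
    mean(cs$bidirectional$S[disk_mask(c(w, w), c(0.5, 0.5), 0.25 * 0.75)])
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  expect_true(all(means > 0))
})

test_that("simulate_ct writes a reconstructable scan with rotational consistency", {
  n <- 64L
  vol <- phantom_cylinder(n, radius_frac = 0.22, value = 0.01, height_frac = 0.7)
  cfg <- noiseless_cfg(c(n, n), photons = 1e4)
  mask <- mask_spec(6)
  root <- file.path(withr::local_tempdir(), "ctscan")
  proj <- simulate_ct(vol, n_angles = 4, mask = mask, cfg = cfg, root = root)

  # a centered homogeneous cylinder projects identically at every angle
  stacks <- lapply(1:4, function(i) {
    load_stack(file.path(proj$categories[["sample"]], sprintf("angle_%05d", i)),
               "sample")$frames[[1]]$pixels
  })
  for (i in 2:4) {
    # bilinear resampling jitters hard cylinder edges by a few percent at
    # single pixels; the bulk of the projection must agree much tighter
    expect_lt(mean(abs(stacks[[i]] - stacks[[1]])) / max(stacks[[1]]), 0.01)
    expect_lt(max(abs(stacks[[i]] - stacks[[1]])) / max(stacks[[1]]), 0.10)
  }
  expect_true(file.exists(file.path(proj$root, "angles.yml")))
  expect_true(file.exists(file.path(proj$root, "ground_truth",
                                    "angle_00001_mu_d.tif")))
})

test_that("an off-center body's projected centroid traces the angle sinusoid", {
  n <- 64L
  mu <- array(0, c(n, n, n))
  yc <- 0.42 * n; xc <- 0.62 * n
  for (z in 20:44) {
    sl <- matrix(0, n, n)
    sl[disk_mask(c(n, n), c(yc / n, xc / n), 0.08)] <- 0.02
    mu[, , z] <- sl
  }
  vol <- phantom_volume(mu)
  angles <- c(0, 45, 90, 135)
  t_axis <- seq_len(n) - (n + 1) / 2
  cx <- xc - (n + 1) / 2; cy <- yc - (n + 1) / 2
  for (a in seq_along(angles)) {
    prof <- radon_transform(mu[, , 32], angles[a])
    centroid <- sum(t_axis * prof) / sum(prof)
    th <- angles[a] * pi / 180
    expect_equal(centroid, cx * cos(th) + cy * sin(th), tolerance = 0.2)
  }
})

test_that("a full simulated scan reconstructs the cylinder density", {
  n <- 96L
  vol <- phantom_cylinder(n, radius_frac = 0.25, value = 0.008, height_frac = 0.6)
  cfg <- noiseless_cfg(c(n, n), photons = 1e4)
  mask <- mask_spec(6)
  root <- file.path(withr::local_tempdir(), "ctrecon")
  proj <- simulate_ct(vol, n_angles = 40, mask = mask, cfg = cfg, root = root)
  shi_ct_prep(proj, expected_period_px = 6)
  sino3 <- assemble_sinogram(proj, c(0L, 0L), "absorption")
  w <- dim(sino3$values)[2]
  k <- ceiling(w / 2)
  rec <- fbp_reconstruct(sinogram(sino3$values[, k, ], sino3$angles_deg))
  true_density <- 0.008 * n / w  # per harmonic-map pixel
  interior <- disk_mask(c(w, w), c(0.5, 0.5), 0.25 * 0.7)
  expect_equal(mean(rec[interior]), true_density, tolerance = 0.05)
})
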