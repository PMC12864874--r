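validated_geom <- function() geometry(68, 71, 318, 49.5, 50)

test_that("geometry validates distances and the projected period", {
  expect_error(geometry(-1, 71, 318, 49.5, 50), "positive")
  expect_error(geometry(80, 71, 318, 49.5, 50), "d1 <= d2")
  expect_error(geometry(68, 71, 70, 49.5, 50), "must exceed")
  expect_error(geometry(68, 71, 318, 49.5, 20), "Nyquist")
  g <- geometry(71, 68, 318, 49.5, 50, optic_upstream = FALSE)
  expect_s3_class(g, "shi_geometry")
})

test_that("effective pixel size follows the worked configuration and scales correctly", {
  g <- validated_geom()
  expect_equal(effective_pixel_size(g), 51.7, tolerance = 0.05 / 51.7)
  # D1 = D2 leaves the pitch unchanged
  gd <- geometry(70, 70, 318, 49.5, 50)
  expect_equal(effective_pixel_size(gd), 49.5)
  # homogeneous of degree 1 in pixel pitch; invariant to common distance scaling
  for (c in c(0.5, 2, 3.7)) {
    g1 <- geometry(68, 71, 318, 49.5 * c, 50 * c)
    expect_equal(effective_pixel_size(g1), c * effective_pixel_size(g))
    g2 <- geometry(68 * c, 71 * c, 318 * c, 49.5, 50)
    expect_equal(effective_pixel_size(g2), effective_pixel_size(g))
  }
})

test_that("sample-plane pixel size reproduces the printed configuration value", {
  expect_equal(round(sample_plane_pixel_size(validated_geom())), 11)
  expect_equal(sample_plane_pixel_size(validated_geom()), 49.5 / (318 / 71))
})

test_that("rebinning is the identity in the parallel limit and exact on constants", {
  set.seed(3)
  img <- matrix(0, 128, 128)
  img[disk_mask(c(128, 128), c(0.45, 0.6), 0.2)] <- 0.8
  g_par <- geometry(68, 71, 1e9, 49.5, 50)
  expect_equal(rebin_cone_to_parallel(img, g_par), img,
               tolerance = 1e-9, ignore_attr = TRUE)
  out <- rebin_cone_to_parallel(matrix(0.7, 64, 64), validated_geom())
  expect_equal(out, matrix(0.7, 64, 64), ignore_attr = TRUE)
  # provenance: a second application is refused
  expect_error(rebin_cone_to_parallel(out, validated_geom()), "already been rebinned")
})

test_that("sinogram constructor enforces angle invariants", {
  v <- matrix(0, 4, 8)
  expect_error(sinogram(v, c(0, 10, 10, 20)), "strictly increasing")
  expect_error(sinogram(v, c(0, 10, 20, 180)), "\\[0, 180\\)")
  expect_error(sinogram(v[1, , drop = FALSE], 0), "at least 2")
  s <- sinogram(v, c(0, 45, 90, 135))
  expect_s3_class(s, "shi_sinogram")
})

test_that("assemble_sinogram sorts by encoded angle and reports missing angles", {
  proj <- init_project(file.path(withr::local_tempdir(), "ct"), "ct")
  angles <- (0:7) * 180 / 8
  set.seed(6)
  imgs <- lapply(1:8, function(i) matrix(i + rnorm(16 * 16), 16, 16))
  for (i in sample(8)) {  # shuffled write order
    write_image(imgs[[i]], ct_output_path(proj, i, c(0L, 0L), "absorption"),
                bits = 32L)
  }
  yaml::write_yaml(list(angles_deg = as.list(angles)),
                   file.path(proj$root, "angles.yml"))
  sino <- assemble_sinogram(proj, c(0L, 0L), "absorption")
  expect_equal(sino$angles_deg, angles)
  for (i in 1:8) expect_equal(sino$values[i, , ], imgs[[i]], tolerance = 1e-6)

  file.remove(ct_output_path(proj, 5L, c(0L, 0L), "absorption"))
  expect_error(assemble_sinogram(proj, c(0L, 0L), "absorption"), "5")
})

test_that("FBP recovers an analytic disk and is linear", {
  n <- 129
  img <- matrix(0, n, n)
  img[disk_mask(c(n, n), c(0.5, 0.5), 0.3)] <- 1
  angles <- seq(0, 179, by = 1)
  sino <- radon_transform(img, angles)
  rec <- fbp_reconstruct(sino, angles_deg = angles)
  interior <- disk_mask(c(n, n), c(0.5, 0.5), 0.24)
  expect_equal(mean(rec[interior]), 1, tolerance = 0.05)
  outside <- !disk_mask(c(n, n), c(0.5, 0.5), 0.4)
  expect_lt(mean(abs(rec[outside])), 0.05)

  expect_equal(fbp_reconstruct(sino * 0, angles_deg = angles), matrix(0, n, n))
  expect_equal(fbp_reconstruct(sino * 3, angles_deg = angles), 3 * rec,
               tolerance = 1e-12)
  expect_error(fbp_reconstruct(sino, center = 500, angles_deg = angles),
               "outside the detector")
})

test_that("the radon forward model is rotation equivariant", {
  n <- 65
  img <- matrix(0, n, n)
  img[disk_mask(c(n, n), c(0.35, 0.6), 0.1)] <- 1
  rot90 <- t(img)[n:1, ]
  for (th in c(0, 20, 45, 70)) {
    expect_equal(radon_transform(rot90, th), radon_transform(img, th + 90),
                 tolerance = 1e-9)
  }
  # projected centroid of an off-center blob traces the analytic sinusoid
  angles <- c(0, 45, 90, 135)
  sino <- radon_transform(img, angles)
  t_axis <- seq_len(n) - (n + 1) / 2
  cx <- 0.6 * n - (n + 1) / 2
  cy <- 0.35 * n - (n + 1) / 2
  for (a in seq_along(angles)) {
    th <- angles[a] * pi / 180
    centroid <- sum(t_axis * sino[a, ]) / sum(sino[a, ])
    expect_equal(centroid, cx * cos(th) + cy * sin(th), tolerance = 0.15)
  }
})

test_that("quality metrics satisfy their identities and closed forms", {
  set.seed(42)
  a <- matrix(rnorm(64 * 64), 64, 64)
  a <- t(apply(apply(a, 2, cumsum), 1, cumsum))  # smooth field

  m <- quality_metrics(a, a)
  expect_identical(m$nrmse, 0)
  expect_identical(m$psnr_db, Inf)
  expect_equal(m$mssim, 1)
  expect_equal(m$nmi, 2)

  sd_n <- 0.02 * (max(a) - min(a))
  noisy <- a + matrix(rnorm(64 * 64, sd = sd_n), 64, 64)
  m2 <- quality_metrics(noisy, a)
  expect_equal(m2$nrmse, sd_n / (max(a) - min(a)), tolerance = 0.05)
  expect_equal(m2$psnr_db, 10 * log10((max(a) - min(a))^2 / mean((noisy - a)^2)))

  # independent white noise: no structure, no information shared (the
  # finite-sample NMI bias shrinks with pixel count, hence the 128^2 grid)
  x <- matrix(rnorm(128 * 128), 128, 128)
  y <- matrix(rnorm(128 * 128), 128, 128)
  m3 <- quality_metrics(x, y)
  expect_lt(abs(m3$mssim), 0.05)
  expect_lt(m3$nmi, 1.15)
  # brute-force histogram/entropy oracle for NMI
  nb <- 256
  bx <- pmin(nb, 1 + floor((x - min(x)) / (max(x) - min(x)) * nb))
  by <- pmin(nb, 1 + floor((y - min(y)) / (max(y) - min(y)) * nb))
  H <- function(tab) { p <- tab[tab > 0] / sum(tab); -sum(p * log(p)) }
  nmi_oracle <- (H(table(bx)) + H(table(by))) / H(table(paste(bx, by)))
  expect_equal(m3$nmi, nmi_oracle, tolerance = 1e-10)

  expect_error(quality_metrics(x, y[1:32, ]), "shape")
  expect_error(quality_metrics(x, matrix(1, 128, 128)), "constant")
})

test_that("reconstruction quality improves monotonically with projection count", {
  n <- 129
  img <- matrix(0, n, n)
  img[disk_mask(c(n, n), c(0.5, 0.55), 0.25)] <- 1
  img[disk_mask(c(n, n), c(0.35, 0.4), 0.08)] <- 2
  angles <- seq(0, 179.5, length.out = 180)
  sino <- sinogram(radon_transform(img, angles), angles)

  study <- projection_count_study(sino, c(90, 18, 180, 45))
  expect_identical(study$n, c(18L, 45L, 90L, 180L))  # keyed by n, input order free
  expect_true(all(diff(study$nrmse) <= 0))
  expect_true(all(diff(study$psnr_db) >= 0))
  expect_true(all(diff(study$mssim) >= 0))
  expect_true(all(diff(study$nmi) >= 0))
  # the full count reproduces the reference exactly
  expect_equal(study$nrmse[4], 0)
  expect_equal(study$mssim[4], 1)
  expect_equal(study$nmi[4], 2)
  expect_error(projection_count_study(sino, c(10, 500)), "counts")
})
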