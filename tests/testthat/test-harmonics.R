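test_that("forward_spectrum concentrates a constant at the center bin and inverts", {
  x <- matrix(3.5, 32, 48)
  sp <- forward_spectrum(x)
  cb <- floor(dim(x) / 2) + 1L
  expect_equal(Mod(sp$values[cb[1], cb[2]]), 3.5 * 32 * 48)
  off <- Mod(sp$values); off[cb[1], cb[2]] <- 0
  expect_lt(max(off), 1e-8)

  set.seed(2)
  y <- matrix(rnorm(64 * 40), 64, 40)
  back <- inverse_spectrum(forward_spectrum(y))
  expect_lt(max(Mod(back - y)) / max(abs(y)), 1e-10)
  # Parseval: spectral energy equals image energy
  spy <- forward_spectrum(y)
  expect_equal(sum(Mod(spy$values)^2) / prod(dim(y)), sum(y^2),
               tolerance = 1e-8)
  bad <- y; bad[1, 1] <- Inf
  expect_error(forward_spectrum(bad), "finite")
})

test_that("a pure cosine produces exactly two symmetric off-center peaks", {
  N <- 256
  img <- matrix(2 + cos(2 * pi * (0:(N - 1)) / 8), N, N, byrow = TRUE)
  sp <- forward_spectrum(img)
  mag <- Mod(sp$values)
  cb <- floor(c(N, N) / 2) + 1L
  expect_equal(mag[cb[1], cb[2]], 2 * N * N)
  # analytic DFT of cosine: A/2 * N * M at column offsets +-N/8
  expect_equal(mag[cb[1], cb[2] + 32], 0.5 * N * N)
  expect_equal(mag[cb[1], cb[2] - 32], 0.5 * N * N)
  rest <- mag
  rest[cb[1], c(cb[2] - 32, cb[2], cb[2] + 32)] <- 0
  expect_lt(max(rest), 1e-6)
})

test_that("detect_peaks reproduces the analytic mesh lattice and the brute-force oracle", {
  mask <- mask_spec(8, edge_sigma = 0)
  pat <- render_mask(mask, c(512, 512))
  sp <- forward_spectrum(pat)
  meta <- detect_peaks(sp)
  expect_equal(meta$d, 8)
  expect_equal(meta$band_limit, 32L)
  cb <- c(257L, 257L)
  for (m in -1:1) for (n in -1:1) {
    got <- meta$peaks[[sprintf("%+d%+d", m, n)]]$center
    expect_identical(got, c(cb[1] - n * 64L, cb[2] - m * 64L))
  }
  oracle <- brute_force_peaks(sp$values, c(512L, 512L), 8)
  for (k in names(meta$peaks)) {
    expect_identical(meta$peaks[[k]]$center, oracle[[k]])
  }
  # supplying the expected period gives the same lattice
  meta2 <- detect_peaks(sp, expected_period_px = 8)
  for (k in names(meta$peaks)) {
    expect_identical(meta2$peaks[[k]]$center, meta$peaks[[k]]$center)
  }
})

test_that("peak centers and band limit are invariant under pattern translation", {
  mask <- mask_spec(8, edge_sigma = 0)
  pat <- render_mask(mask, c(256, 256))
  rolled <- render_mask(mask_spec(8, offset = c(3, 0), edge_sigma = 0), c(256, 256))
  m1 <- detect_peaks(forward_spectrum(pat))
  m2 <- detect_peaks(forward_spectrum(rolled))
  expect_identical(m2$band_limit, m1$band_limit)
  for (k in names(m1$peaks)) {
    expect_identical(m2$peaks[[k]]$center, m1$peaks[[k]]$center)
  }
})

test_that("sub-Nyquist periods are rejected", {
  expect_error(mask_spec(2.5), "Nyquist")
  N <- 512
  wave <- cos(2 * pi * (0:(N - 1)) / 2.5)
  img <- 1 + 0.3 * matrix(wave, N, N, byrow = TRUE) * matrix(wave, N, N)
  expect_error(detect_peaks(forward_spectrum(img)), "Nyquist")
  expect_error(detect_peaks(forward_spectrum(img), expected_period_px = 2.5),
               "Nyquist")
})

test_that("extract_harmonic recovers analytic amplitudes and shift-theorem phases", {
  N <- 256
  # (0,0) of a constant image: the constant, purely real
  spc <- forward_spectrum(matrix(1.25, N, N))
  cb <- floor(c(N, N) / 2) + 1L
  h00 <- extract_harmonic(spc, list(label = c(0L, 0L), center = cb), 16L)
  expect_equal(Re(h00$values), matrix(1.25, 33, 33), tolerance = 1e-10)
  expect_lt(max(abs(Im(h00$values))), 1e-10)

  # (1,0) of A*cos(2 pi x / 8): constant modulus A/2
  A <- 0.8
  cosx <- function(delta) {
    matrix(2 + A * cos(2 * pi * ((0:(N - 1)) - delta) / 8), N, N, byrow = TRUE)
  }
  sp0 <- forward_spectrum(cosx(0))
  pk <- list(label = c(1L, 0L), center = c(cb[1], cb[2] - 32L))
  h1 <- extract_harmonic(sp0, pk, 15L)
  expect_equal(Mod(h1$values), matrix(A / 2, 31, 31), tolerance = 1e-8)

  # translation by delta: same modulus, phase shifted by 2 pi delta / p
  delta <- 1.7
  h1d <- extract_harmonic(forward_spectrum(cosx(delta)), pk, 15L)
  expect_equal(Mod(h1d$values), Mod(h1$values), tolerance = 1e-8)
  dphi <- Arg(h1d$values / h1$values)
  expect_equal(mean(dphi), wrap_pi(2 * pi * delta / 8), tolerance = 1e-9)
  expect_lt(max(abs(dphi - mean(dphi))), 1e-9)

  # clipped window is refused with advice
  expect_error(extract_harmonic(sp0, pk, 100L), "smaller band limit")
})

test_that("apply_metadata equals per-peak extraction and enforces shape", {
  mask <- mask_spec(8)
  pat <- render_mask(mask, c(256, 256))
  sp <- forward_spectrum(pat)
  meta <- detect_peaks(sp)
  hs <- apply_metadata(sp, meta)
  expect_named(hs, names(meta$peaks))
  for (k in names(hs)) {
    direct <- extract_harmonic(sp, meta$peaks[[k]], meta$band_limit)
    expect_identical(hs[[k]]$values, direct$values)
  }
  small <- forward_spectrum(matrix(1, 128, 128))
  expect_error(apply_metadata(small, meta), "shape")
})

test_that("opposite labels are complex conjugates for real input", {
  mask <- mask_spec(8)
  # structured real input: mask times a smooth envelope
  env <- outer(seq(0.5, 1, length.out = 256), seq(1, 0.6, length.out = 256))
  sp <- forward_spectrum(render_mask(mask, c(256, 256)) * env)
  meta <- detect_peaks(sp)
  hs <- apply_metadata(sp, meta)
  for (pair in list(c("+1+0", "-1+0"), c("+0+1", "+0-1"), c("+1+1", "-1-1"))) {
    a <- hs[[pair[1]]]$values
    b <- hs[[pair[2]]]$values
    expect_lt(max(Mod(a - Conj(b))), 1e-9 * max(Mod(a)))
  }
})

test_that("harmonic metadata survives a JSON round trip", {
  mask <- mask_spec(8)
  sp <- forward_spectrum(render_mask(mask, c(256, 256)))
  meta <- detect_peaks(sp)
  p <- file.path(withr::local_tempdir(), "harmonics.json")
  save_harmonic_meta(meta, p)
  back <- load_harmonic_meta(p)
  expect_equal(back$band_limit, meta$band_limit)
  expect_equal(back$d, meta$d)
  h1 <- apply_metadata(sp, meta)
  h2 <- apply_metadata(sp, back)
  for (k in names(h1)) expect_equal(h2[[k]]$values, h1[[k]]$values)
})
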