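# Shared fixtures, built in code at test time.

# Noiseless detector configuration for analytic-accuracy checks.
noiseless_cfg <- function(shape, seed = 7L, photons = 1e4, gain = 1) {
  sim_config(shape = shape, photons = photons, gain = gain, dark_offset = 0,
             dark_spread = 0, read_sd = 0, shot_noise = FALSE, seed = seed)
}

# Render a reference/sample pair and flat-field both; returns the two
# shi_corrected images (and the raw frames for tests that need them).
corrected_pair <- function(mask, phantom, cfg) {
  fr <- render_frames(mask, phantom, cfg)
  dark <- average_stack(fr$dark)
  bright <- average_stack(fr$bright)
  list(ref = flat_field(average_stack(fr$reference), dark, bright),
       sample = flat_field(average_stack(fr$sample), dark, bright),
       frames = fr)
}

# Stack of constant-valued frames.
const_stack <- function(values, shape = c(16L, 16L), category = "sample") {
  frame_stack(lapply(seq_along(values), function(i) {
    frame(matrix(values[i], shape[1], shape[2]), category = category, index = i)
  }))
}

# Independent oracle: locate all nine harmonic peaks of a mesh spectrum
# by brute-force global maxima over lattice-cell neighborhoods, given the
# true period. Searches the full spectrum, one cell per label, with no
# reuse of the package's lattice-prediction/snapping logic.
brute_force_peaks <- function(spectrum_values, shape, true_period) {
  mag <- Mod(spectrum_values)
  cb <- floor(shape / 2) + 1L
  f_col <- round(shape[2] / true_period)
  f_row <- round(shape[1] / true_period)
  out <- list()
  for (m in -1:1) for (n in -1:1) {
    ctr <- c(cb[1] - n * f_row, cb[2] - m * f_col)
    rows <- max(1, ctr[1] - floor(f_row / 2) + 1):min(shape[1], ctr[1] + floor(f_row / 2) - 1)
    cols <- max(1, ctr[2] - floor(f_col / 2) + 1):min(shape[2], ctr[2] + floor(f_col / 2) - 1)
    sub <- mag[rows, cols, drop = FALSE]
    idx <- arrayInd(which.max(sub), dim(sub))
    out[[sprintf("%+d%+d", m, n)]] <- c(rows[idx[1]], cols[idx[2]])
  }
  out
}

wrap_pi <- function(x) x - 2 * pi * round(x / (2 * pi))
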