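# Internal FFT/array helpers. Centered-spectrum convention: the
# zero-frequency bin sits at (floor(n/2), floor(m/2)) in 0-based
# coordinates, i.e. row/col floor(n/2)+1 in R's 1-based indexing.

roll2 <- function(x, r, c) {
  n1 <- nrow(x); n2 <- ncol(x)
  i <- ((seq_len(n1) - 1L - r) %% n1) + 1L
  j <- ((seq_len(n2) - 1L - c) %% n2) + 1L
  x[i, j, drop = FALSE]
}

fftshift2 <- function(x) roll2(x, floor(nrow(x) / 2), floor(ncol(x) / 2))
ifftshift2 <- function(x) roll2(x, -floor(nrow(x) / 2), -floor(ncol(x) / 2))

center_bin <- function(shape) floor(shape / 2) + 1L  # 1-based

# Bilinear interpolation of matrix z at fractional (row, col) positions.
# Queries outside the grid return `fill`, or the nearest border value
# when clamp = TRUE (used where the remap overshoots the rim by a
# sub-pixel amount).
bilinear_interp <- function(z, r, c, fill = 0, clamp = FALSE) {
  n1 <- nrow(z); n2 <- ncol(z)
  out <- rep(fill, length(r))
  inside <- if (clamp) rep(TRUE, length(r)) else
    r >= 1 & r <= n1 & c >= 1 & c <= n2
  r <- pmin(pmax(r[inside], 1), n1)
  c <- pmin(pmax(c[inside], 1), n2)
  r0 <- pmin(floor(r), n1 - 1L); c0 <- pmin(floor(c), n2 - 1L)
  fr <- r - r0; fc <- c - c0
  v00 <- z[cbind(r0, c0)];         v01 <- z[cbind(r0, c0 + 1L)]
  v10 <- z[cbind(r0 + 1L, c0)];    v11 <- z[cbind(r0 + 1L, c0 + 1L)]
  out[inside] <- (1 - fr) * ((1 - fc) * v00 + fc * v01) +
    fr * ((1 - fc) * v10 + fc * v11)
  out
}

# Gaussian blur via the frequency domain (exact Gaussian transfer
# function, periodic boundary). sigma in pixels.
gaussian_blur_fft <- function(x, sigma) {
  if (sigma <= 0) return(x)
  n1 <- nrow(x); n2 <- ncol(x)
  fr <- c(0:(floor(n1 / 2)), -(ceiling(n1 / 2) - 1):-1) / n1
  fc <- c(0:(floor(n2 / 2)), -(ceiling(n2 / 2) - 1):-1) / n2
  h <- exp(-2 * pi^2 * sigma^2 * outer(fr^2, fc^2, `+`))
  Re(stats::fft(stats::fft(x) * h, inverse = TRUE)) / (n1 * n2)
}

# Box-filter local mean with "valid" output (window fully inside), via
# integral images. k must be odd.
box_mean_valid <- function(x, k) {
  n1 <- nrow(x); n2 <- ncol(x)
  stopifnot(k %% 2 == 1, n1 >= k, n2 >= k)
  s <- apply(apply(x, 2, cumsum), 1, cumsum)  # transposed cumulative sum
  s <- t(s)
  pad <- matrix(0, n1 + 1L, n2 + 1L)
  pad[-1L, -1L] <- s
  i <- seq_len(n1 - k + 1L); j <- seq_len(n2 - k + 1L)
  (pad[i + k, j + k, drop = FALSE] - pad[i, j + k, drop = FALSE] -
     pad[i + k, j, drop = FALSE] + pad[i, j, drop = FALSE]) / (k * k)
}

# Run code with a private, restorable RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
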