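# Synthetic test surfaces used across the suite.

sinusoid_hm <- function(n = 512, dx = 1.5625, lambda = 100, amp = 1) {
  x <- (seq_len(n) - 1) * dx
  height_map(matrix(amp * sin(2 * pi * x / lambda), n, n, byrow = TRUE),
             dx = dx)
}

ramp_hm <- function(n = 256, dx = 1.5625, zmax = 10) {
  height_map(matrix(seq(0, zmax, length.out = n), n, n, byrow = TRUE),
             dx = dx)
}

paraboloid_hm <- function(n = 129, dx = 1.5625, R = 50, h = 10) {
  xs <- (seq_len(n) - (n + 1) / 2) * dx
  z <- h - (outer(xs^2, rep(1, n)) + outer(rep(1, n), xs^2)) / (2 * R)
  height_map(z, dx = dx)
}

# smooth random surface: white noise convolved with a Gaussian kernel in
# the frequency domain (independent of the package's field generator)
smooth_noise_hm <- function(n = 64, dx = 1.5625, corr_px = 3, seed = 1) {
  set.seed(seed)
  wn <- matrix(rnorm(n * n), n, n)
  f <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[seq_len(n)] / n
  H <- exp(-2 * pi^2 * corr_px^2 * outer(f^2, f^2, `+`))
  z <- Re(fft(fft(wn) * H, inverse = TRUE)) / n^2
  height_map(z / sd(z), dx = dx)
}

white_noise_hm <- function(n = 256, dx = 1.5625, seed = 1) {
  set.seed(seed)
  height_map(matrix(rnorm(n * n), n, n), dx = dx)
}
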