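# Shared helpers and independent oracles for the test suite.  These
# deliberately avoid the package's own resampling/convolution paths.

rel_l2 <- function(x, ref) {
  d <- sqrt(sum((x - ref)^2)); n <- sqrt(sum(ref^2))
  if (n == 0) return(if (d == 0) 0 else Inf)
  d / n
}

freq_idx <- function(n) { k <- seq_len(n) - 1L; k[k > n / 2] <- k[k > n / 2] - n; k }

fft2o <- function(x) t(stats::mvfft(t(stats::mvfft(x))))
ifft2o <- function(x) t(stats::mvfft(t(stats::mvfft(x, inverse = TRUE)),
                                     inverse = TRUE)) / length(x)

# Independent circular convolution with kernel centered at ((n+1)/2).
conv2o <- function(img, ker, correlate = FALSE) {
  n <- nrow(img)
  ky <- freq_idx(n) / n
  ramp <- exp(2i * pi * (outer(ky * ((n + 1) / 2 - 1), ky * ((n + 1) / 2 - 1), "+")))
  kh <- fft2o(ker) * ramp
  if (correlate) kh <- Conj(kh)
  Re(ifft2o(fft2o(img) * kh))
}

# Smooth band-limited test image: mixture of Gaussian blobs with an
# interior support margin.
smooth_blobs <- function(N, seed = 1, n_blobs = 8, sigma = 2.5, margin = 4) {
  set.seed(seed)
  img <- matrix(0, N, N)
  for (i in seq_len(n_blobs)) {
    r0 <- runif(1, margin, N - margin + 1)
    c0 <- runif(1, margin, N - margin + 1)
    a <- runif(1, 0.3, 1)
    img <- img + a * outer(1:N, 1:N, function(r, c)
      exp(-((r - r0)^2 + (c - c0)^2) / (2 * sigma^2)))
  }
  img / max(img)
}

# Exact rotation for band-limited images: three FFT shears about the
# matrix center ((n+1)/2), composed with exact 90-degree rotations.
shear_cols <- function(img, s) {
  n <- ncol(img); ctr <- (nrow(img) + 1) / 2
  kx <- freq_idx(n) / n
  sh <- s * (seq_len(nrow(img)) - ctr)
  out <- t(stats::mvfft(t(img)))
  out <- out * exp(-2i * pi * outer(sh, kx))
  Re(t(stats::mvfft(t(out), inverse = TRUE))) / n
}
rot90o <- function(m) t(m)[, nrow(m):1]
rotate_fft <- function(img, ang) {
  ang <- ang %% (2 * pi)
  k <- round(ang / (pi / 2)); resid <- ang - k * (pi / 2); k <- k %% 4
  for (i in seq_len(k)) img <- rot90o(img)
  if (abs(resid) > 1e-12) {
    a <- -tan(resid / 2); b <- sin(resid)
    img <- shear_cols(img, a)
    img <- t(shear_cols(t(img), b))
    img <- shear_cols(img, a)
  }
  img
}

# Bilinear rotation about the matrix center (independent resampling).
rotate_bilinear <- function(img, ang) {
  N <- nrow(img); ctr <- (N + 1) / 2
  rows <- matrix(1:N, N, N) - ctr
  cols <- matrix(1:N, N, N, byrow = TRUE) - ctr
  rr <- cos(ang) * rows - sin(ang) * cols + ctr
  cc <- sin(ang) * rows + cos(ang) * cols + ctr
  r0 <- floor(rr); c0 <- floor(cc)
  fr <- rr - r0; fc <- cc - c0
  out <- matrix(0, N, N)
  for (dr in 0:1) for (dc in 0:1) {
    ri <- r0 + dr; ci <- c0 + dc
    w <- (if (dr == 0) 1 - fr else fr) * (if (dc == 0) 1 - fc else fc)
    ok <- ri >= 1 & ri <= N & ci >= 1 & ci <= N
    out[ok] <- out[ok] + w[ok] * img[cbind(ri[ok], ci[ok])]
  }
  out
}

# Second-moment matrix of an image about its centroid.
second_moments <- function(img) {
  s <- sum(img)
  cy <- sum(row(img) * img) / s; cx <- sum(col(img) * img) / s
  myy <- sum((row(img) - cy)^2 * img) / s
  mxx <- sum((col(img) - cx)^2 * img) / s
  mxy <- sum((row(img) - cy) * (col(img) - cx) * img) / s
  matrix(c(myy, mxy, mxy, mxx), 2, 2)
}

psnr_of <- function(x, ref) 10 * log10(max(ref)^2 / mean((x - ref)^2))

# Circular 3D convolution with a centered kernel (independent oracle).
conv3o <- function(vol, ker_small) {
  dims <- dim(vol)
  emb <- array(0, dims)
  dp <- dim(ker_small)
  emb[seq_len(dp[1]), seq_len(dp[2]), seq_len(dp[3])] <- ker_small
  ctr <- (dp + 1) / 2
  kx <- freq_idx(dims[1]) / dims[1]
  ky <- freq_idx(dims[2]) / dims[2]
  kz <- freq_idx(dims[3]) / dims[3]
  ph <- array(0, dims)
  for (ix in seq_len(dims[1]))
    ph[ix, , ] <- kx[ix] * (ctr[1] - 1) +
      outer(ky * (ctr[2] - 1), kz * (ctr[3] - 1), "+")
  Hh <- fft(emb) * exp(2i * pi * ph)
  Re(fft(fft(vol) * Hh, inverse = TRUE)) / prod(dims)
}
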