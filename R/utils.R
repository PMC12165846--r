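# Internal numerical helpers shared across modules.

fft2 <- function(x) stats::fft(x)

ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# DFT frequency indices 0, 1, ..., -1 (cycles per full window).
freq_index <- function(n) {
  k <- seq_len(n) - 1L
  k[k > n / 2] <- k[k > n / 2] - n
  k
}

fftshift2 <- function(x) {
  d <- dim(x)
  x[c(seq(floor(d[1] / 2) + 1, d[1]), seq_len(floor(d[1] / 2))),
    c(seq(floor(d[2] / 2) + 1, d[2]), seq_len(floor(d[2] / 2)))]
}

# Circular 2D convolution of `img` with a kernel whose center sits at
# `center` (1-based, possibly fractional).  The fractional part is applied
# exactly through a Fourier phase ramp.
conv2_centered <- function(img, kernel, center = (dim(kernel) + 1) / 2,
                           correlate = FALSE) {
  stopifnot(all(dim(img) == dim(kernel)))
  n <- dim(img)
  ky <- freq_index(n[1]) / n[1]
  kx <- freq_index(n[2]) / n[2]
  # shift kernel so its center moves to index (1,1)
  ramp <- exp(2i * pi * (outer(ky * (center[1] - 1), kx * (center[2] - 1), "+")))
  kh <- fft2(kernel) * ramp
  if (correlate) kh <- Conj(kh)
  Re(ifft2(fft2(img) * kh))
}

# Translate an image by (dy, dx) pixels (fractional allowed) via the Fourier
# shift theorem.  Content wraps circularly.
fourier_shift <- function(img, dy, dx) {
  n <- dim(img)
  ky <- freq_index(n[1]) / n[1]
  kx <- freq_index(n[2]) / n[2]
  ramp <- exp(-2i * pi * outer(ky * dy, kx * dx, "+"))
  Re(ifft2(fft2(img) * ramp))
}

# Vectorised bilinear sampling of a matrix at fractional (row, col)
# positions (1-based).  Samples falling outside the matrix return 0.
bilinear_sample <- function(img, rows, cols) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0;   fc <- cols - c0
  out <- numeric(length(rows))
  for (dr in 0:1) for (dc in 0:1) {
    ri <- r0 + dr; ci <- c0 + dc
    w <- (if (dr == 0) 1 - fr else fr) * (if (dc == 0) 1 - fc else fc)
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc & w > 0
    if (any(ok)) out[ok] <- out[ok] + w[ok] * img[cbind(ri[ok], ci[ok])]
  }
  out
}

rel_l2 <- function(x, ref) {
  d <- sqrt(sum((x - ref)^2))
  n <- sqrt(sum(ref^2))
  if (n == 0) return(if (d == 0) 0 else Inf)
  d / n
}

#' Peak signal-to-noise ratio
#'
#' PSNR in decibels of an estimate against a reference, using the
#' reference's maximum as the peak value.
#'
#' @param x estimate (array of any shape).
#' @param ref reference of the same shape.
#' @return PSNR in dB.
#' @export
psnr <- function(x, ref) {
  mse <- mean((x - ref)^2)
  if (mse == 0) return(Inf)
  10 * log10(max(ref)^2 / mse)
}

# Run code with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards, so generators are pure functions of the seed.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
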