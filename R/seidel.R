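# Seidel pupil model: wavefronts and field-dependent PSFs for rotationally
# symmetric systems, parameterized by the five primary aberration
# coefficients (in waves).

#' Primary Seidel aberration coefficients
#'
#' Container for the five primary (fourth-order) Seidel coefficients, in
#' waves: spherical aberration, coma, astigmatism, field curvature and
#' distortion.  These parameterize the wavefront error of a rotationally
#' symmetric system as an explicit function of field position, so a single
#' five-vector describes the point spread function everywhere in the field
#' of view.
#'
#' @param sphere,coma,astigmatism,field_curvature,distortion coefficients
#'   in waves (finite reals).
#' @return an object of class `seidel_coefficients` (a named numeric
#'   vector of length 5).
#' @examples
#' seidel_coefficients(sphere = 1, coma = 0.5)
#' @export
seidel_coefficients <- function(sphere = 0, coma = 0, astigmatism = 0,
                                field_curvature = 0, distortion = 0) {
  w <- c(sphere = sphere, coma = coma, astigmatism = astigmatism,
         field_curvature = field_curvature, distortion = distortion)
  if (!all(is.finite(w)))
    stop("Seidel coefficients must be finite numbers")
  structure(as.numeric(w), names = names(w), class = "seidel_coefficients")
}

#' @export
print.seidel_coefficients <- function(x, ...) {
  cat("Seidel coefficients (waves):\n")
  print(round(unclass(x), 4))
  invisible(x)
}

as_seidel <- function(w) {
  if (inherits(w, "seidel_coefficients")) return(w)
  w <- as.numeric(w)
  stopifnot(length(w) == 5)
  do.call(seidel_coefficients, as.list(w))
}

#' Euclidean norm of a Seidel coefficient vector
#'
#' Used throughout as the "aberration magnitude" of a system.
#'
#' @param coeffs a [seidel_coefficients] object (or 5-vector).
#' @param off_axis if `TRUE`, include only the field-dependent terms
#'   (coma, astigmatism, field curvature, distortion), the ones that make
#'   a system deviate from space invariance.
#' @return nonnegative scalar, in waves.
#' @export
seidel_norm <- function(coeffs, off_axis = FALSE) {
  w <- unclass(as_seidel(coeffs))
  if (off_axis) w <- w[-1]
  sqrt(sum(w^2))
}

#' Optical simulation grid
#'
#' Describes the sampling used by the pupil-function PSF engine: image
#' side length, padding of the pupil grid, and the maximum field radius
#' used to normalize field height.
#'
#' The pupil's unit disc spans a fraction `pupil_fill` of the padded
#' grid's half-side.  The default 0.5 makes the PSF *intensity* exactly
#' band-limited on the grid (the intensity spectrum is the
#' autocorrelation of the pupil, with twice its support), giving a
#' diffraction-limited core of about 5 pixels and alias-free sampling;
#' everything is in normalized (wavelength-free) units.
#'
#' @param N image side length in pixels (>= 8).
#' @param pad_factor integer >= 1; pupil grid side = `N * pad_factor`.
#' @param r_max maximum field radius in pixels; field height is
#'   `H = r / r_max`.  Defaults to the image half-diagonal, so the corner
#'   of the field of view has `H = 1`.
#' @param pixel_pitch physical size of a pixel (arbitrary units).
#' @param pupil_fill pupil disc radius as a fraction of the padded
#'   grid's half-side, in `(0, 1]`.
#' @return an object of class `optical_grid`.
#' @export
optical_grid <- function(N, pad_factor = 2, r_max = N * sqrt(2) / 2,
                         pixel_pitch = 1, pupil_fill = 0.5) {
  stopifnot(N >= 8, pad_factor >= 1, r_max > 0,
            pupil_fill > 0, pupil_fill <= 1)
  structure(list(N = as.integer(N), pad_factor = as.integer(pad_factor),
                 pupil_samples = as.integer(N * pad_factor),
                 r_max = r_max, pixel_pitch = pixel_pitch,
                 pupil_fill = pupil_fill),
            class = "optical_grid")
}

# Cache of pupil coordinate maps keyed by grid side length and fill.
.pupil_cache <- new.env(parent = emptyenv())

# Pupil-plane coordinate maps for an L x L grid with the unit disc
# spanning `fill` of the half-side.  Returns the disc mask and the
# monomial maps entering the primary Seidel wavefront, restricted to the
# disc (as vectors) for speed.
pupil_basis <- function(L, fill = 0.5) {
  key <- paste(L, fill)
  if (!is.null(.pupil_cache[[key]])) return(.pupil_cache[[key]])
  half <- L * fill / 2
  u <- (seq_len(L) - 1 - floor(L / 2)) / half   # normalized, disc = |u| <= 1
  X <- matrix(u, L, L, byrow = TRUE)           # rho * cos(phi), column dir
  Y <- matrix(u, L, L)                         # rho * sin(phi), row dir
  rho2 <- X^2 + Y^2
  mask <- rho2 <= 1
  idx <- which(mask)
  b <- list(L = L, fill = fill, mask = mask, idx = idx,
            X = X[idx], Y = Y[idx],
            rho2 = rho2[idx], rho4 = rho2[idx]^2,
            # centered pupil indices for positional phase ramps
            my = matrix(seq_len(L) - 1 - floor(L / 2), L, L)[idx],
            mx = matrix(seq_len(L) - 1 - floor(L / 2), L, L, byrow = TRUE)[idx])
  .pupil_cache[[key]] <- b
  b
}

# Wavefront values (waves) on the pupil-disc samples for field height H at
# field angle theta.  Returns a vector aligned with pupil_basis(L)$idx.
seidel_wavefront_values <- function(coeffs, H, theta, b) {
  w <- unclass(as_seidel(coeffs))
  cpsi <- cos(theta) * b$X + sin(theta) * b$Y   # rho * cos(phi - theta)
  w[["sphere"]] * b$rho4 +
    w[["coma"]] * H * b$rho2 * cpsi +
    w[["astigmatism"]] * H^2 * cpsi^2 +
    w[["field_curvature"]] * H^2 * b$rho2 +
    w[["distortion"]] * H^3 * cpsi
}

#' Seidel wavefront error map
#'
#' Evaluates the classical primary (fourth-order) wavefront polynomial
#' \deqn{W(\rho,\phi) = w_{040}\rho^4 + w_{131} H \rho^3\cos(\phi-\theta)
#'   + w_{222} H^2 \rho^2\cos^2(\phi-\theta) + w_{220} H^2 \rho^2
#'   + w_{311} H^3 \rho\cos(\phi-\theta)}
#' over the unit pupil disc, in waves, for a source at normalized field
#' height `H` and field angle `theta`.
#'
#' @param coeffs [seidel_coefficients].
#' @param H normalized field height in `[0, 1]`.
#' @param theta field angle in radians.
#' @param grid an [optical_grid].
#' @return list with `phase` (pupil-grid matrix, zero outside the disc)
#'   and `mask` (logical disc support).
#' @export
seidel_wavefront <- function(coeffs, H, theta, grid) {
  stopifnot(inherits(grid, "optical_grid"))
  if (!is.finite(H) || H < 0 || H > 1)
    stop("field height H must lie in [0, 1]")
  b <- pupil_basis(grid$pupil_samples, grid$pupil_fill)
  phase <- matrix(0, b$L, b$L)
  phase[b$idx] <- seidel_wavefront_values(coeffs, H, theta, b)
  list(phase = phase, mask = b$mask)
}

# Core PSF renderer on an L x L pupil grid.  `shift` is the desired
# displacement (rows, cols) of the PSF center from the grid's DC position
# after fftshift; applied exactly as a pupil phase ramp.  Returns the full
# padded intensity pattern (fftshifted, so an unshifted PSF is centered at
# floor(L/2)+1).
render_psf_padded <- function(coeffs, H, theta, L, shift = c(0, 0),
                              fill = 0.5) {
  b <- pupil_basis(L, fill)
  W <- seidel_wavefront_values(coeffs, H, theta, b)
  ramp <- (shift[1] * b$my + shift[2] * b$mx) / L
  P <- matrix(0 + 0i, L, L)
  P[b$idx] <- exp(2i * pi * (W + ramp))
  a <- fft2(P)
  fftshift2(Re(a)^2 + Im(a)^2)
}

#' Render a field-dependent PSF from Seidel coefficients
#'
#' Computes the point spread function of a source at polar position
#' `(r, theta)` about the optical center: the squared modulus of the
#' inverse Fourier transform of the pupil function
#' \eqn{\exp(i 2\pi W(\rho,\phi))}, placed so the unaberrated image point
#' lies at `(r, theta)` (sub-pixel placement is exact, via a pupil phase
#' ramp), then cropped to the `N x N` image.
#'
#' Normalization modes: `"energy"` (default) scales by the total energy
#' leaving the pupil (a Parseval constant of the padded grid), so PSFs at
#' every field position share one physical scale and the in-image sum is
#' at most 1 -- slightly below 1 when part of the pattern falls outside
#' the field of view.  This keeps the rendered system exactly
#' revolution-invariant.  `"sum"` renormalizes the crop to unit sum
#' (convenient for space-invariant deconvolution kernels); `"none"`
#' returns the raw squared modulus.
#'
#' @param coeffs [seidel_coefficients].
#' @param r source radius in pixels (`<= grid$r_max`).
#' @param theta source angle in radians.
#' @param grid an [optical_grid].
#' @param normalize `"energy"`, `"sum"` or `"none"` (logical `TRUE` is
#'   accepted as `"energy"`, `FALSE` as `"none"`).
#' @return `N x N` PSF matrix.  The optical center is at matrix position
#'   `((N+1)/2, (N+1)/2)`.
#' @export
render_psf <- function(coeffs, r, theta, grid, normalize = "energy") {
  stopifnot(inherits(grid, "optical_grid"))
  if (isTRUE(normalize)) normalize <- "energy"
  if (isFALSE(normalize)) normalize <- "none"
  normalize <- match.arg(normalize, c("energy", "sum", "none"))
  if (r > grid$r_max) stop("source radius exceeds r_max (out of field)")
  if (r < 0) stop("source radius must be nonnegative")
  N <- grid$N
  L <- grid$pupil_samples
  H <- r / grid$r_max
  # optical center at ((N+1)/2, (N+1)/2) in 1-based coords
  off <- floor((L - N) / 2)                  # crop offset (0-based)
  cpad <- floor(L / 2) + 1                   # fftshifted DC position
  target_r <- off + (N + 1) / 2 + r * sin(theta)
  target_c <- off + (N + 1) / 2 + r * cos(theta)
  pad <- render_psf_padded(coeffs, H, theta, L,
                           shift = c(target_r - cpad, target_c - cpad),
                           fill = grid$pupil_fill)
  psf <- pad[off + seq_len(N), off + seq_len(N)]
  psf[psf < 0] <- 0
  if (normalize == "energy") {
    # sum over the padded grid = L^2 * (number of pupil samples), by
    # Parseval (|P| = 1 on the disc)
    psf <- psf / (as.numeric(L)^2 *
                    length(pupil_basis(L, grid$pupil_fill)$idx))
  } else if (normalize == "sum") {
    s <- sum(psf)
    if (s <= 0) stop("degenerate PSF (zero energy in field of view)")
    psf <- psf / s
  }
  psf
}

#' Render a radial line of PSFs
#'
#' Generates the kernel bank required by ring convolution: PSFs at `K`
#' radii uniformly spanning `[0, r_max]`, all at field angle 0.  Under
#' revolution invariance these determine the PSF everywhere.
#'
#' @param coeffs [seidel_coefficients].
#' @param grid an [optical_grid].
#' @param K number of radii (>= 2).  Defaults to the value matching the
#'   default polar grid, `ceiling(N * sqrt(2) / 2) + 1`.
#' @param canvas `"field"` (default) renders each PSF on an enlarged
#'   square canvas that contains the whole field disc of radius `r_max`,
#'   so that sources beyond `N/2` along the radial line (which lie
#'   outside the `N x N` image) are still represented without clipping;
#'   `"image"` renders on the `N x N` image canvas (appropriate when
#'   mimicking directly measured PSF images).
#' @return a `radial_psf_stack`: list with `psfs` (list of square
#'   matrices), `radii` (strictly increasing, pixels) and `grid`.
#' @export
render_radial_psf_stack <- function(coeffs, grid,
                                    K = ceiling(grid$N * sqrt(2) / 2) + 1,
                                    canvas = c("field", "image"),
                                    normalize = "energy") {
  stopifnot(inherits(grid, "optical_grid"))
  canvas <- match.arg(canvas)
  if (K < 2) stop("K must be >= 2")
  rgrid <- grid
  if (canvas == "field") {
    # cover the field disc plus half an image of margin so outer-radius
    # PSFs keep their tails (normalization would otherwise inflate them)
    N_ext <- 2 * ceiling(grid$r_max + grid$N / 2) + 1
    if (N_ext > grid$N)
      rgrid <- optical_grid(N_ext, pad_factor = grid$pad_factor,
                            r_max = grid$r_max,
                            pixel_pitch = grid$pixel_pitch,
                            pupil_fill = grid$pupil_fill)
  }
  radii <- seq(0, grid$r_max, length.out = K)
  psfs <- lapply(radii, function(r) render_psf(coeffs, r, 0, rgrid, normalize))
  radial_psf_stack(psfs, radii, grid, image_N = grid$N)
}

#' Construct a radial PSF stack
#'
#' @param psfs list of square full-field PSF images (all the same size),
#'   the `j`-th being the image of a point source at polar position
#'   `(radii[j], 0)` about the canvas center.
#' @param radii strictly increasing radii in pixels.
#' @param grid the [optical_grid] the PSFs live on (optional but
#'   recommended).
#' @param image_N side length of the object/image the stack will be used
#'   with; defaults to the PSF canvas size.  The canvas may be larger
#'   than the image so that PSFs at radii beyond `N/2` are not clipped.
#' @return object of class `radial_psf_stack`.
#' @export
radial_psf_stack <- function(psfs, radii, grid = NULL, image_N = NULL) {
  stopifnot(is.list(psfs), length(psfs) == length(radii))
  if (any(diff(radii) <= 0)) stop("radii must be strictly increasing")
  N <- nrow(psfs[[1]])
  for (p in psfs) {
    stopifnot(is.matrix(p), all(dim(p) == N))
    if (any(p < -1e-9)) stop("PSFs must be nonnegative")
  }
  structure(list(psfs = psfs, radii = as.numeric(radii), N = N,
                 image_N = as.integer(image_N %||% N), grid = grid),
            class = "radial_psf_stack")
}

#' @export
print.radial_psf_stack <- function(x, ...) {
  cat(sprintf("Radial PSF stack: %d PSFs of %dx%d, radii [%.2f, %.2f] px\n",
              length(x$psfs), x$N, x$N, min(x$radii), max(x$radii)))
  invisible(x)
}
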