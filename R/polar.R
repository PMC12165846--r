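# Resampling between Cartesian images and (angle x radius) polar grids
# about the optical center.  Both directions are separable-kernel
# gathers, materialized once per grid as sparse matrices so that forward
# transforms and their exact adjoints (needed by the deconvolution
# gradient) are plain sparse matrix-vector products.

#' Polar grid specification
#'
#' Defines the `(angle x radius)` grid used by the polar transform and by
#' ring convolution.  Angular samples are uniform on `[0, 2*pi)`; radial
#' samples are uniform on `[0, max_radius]`.
#'
#' Defaults: `max_radius` is the image half-diagonal so the grid reaches
#' the corners; `num_radii` gives a radial spacing of about 1 pixel;
#' `num_angles` is the smallest multiple of 4 at least
#' `ceiling(2 * pi * max_radius)`, so the outermost ring is not angularly
#' undersampled.
#'
#' @param N Cartesian image side length (pixels).
#' @param num_angles number of angular samples M (>= 4).
#' @param num_radii number of radial samples K (>= 2).
#' @param center optical center, 1-based (row, col); default the geometric
#'   center `((N+1)/2, (N+1)/2)` (fractional for even N).
#' @param max_radius outermost sampled radius (pixels).
#' @param interp interpolation kernel for both transform directions:
#'   `"cubic"` (Catmull-Rom, the default; sharper, round-trip error well
#'   under 1\% on band-limited images) or `"bilinear"`.
#' @return an object of class `polar_grid_spec`.
#' @export
polar_grid_spec <- function(N, num_angles = NULL, num_radii = NULL,
                            center = NULL, max_radius = NULL,
                            interp = c("cubic", "bilinear")) {
  N <- as.integer(N)
  interp <- match.arg(interp)
  max_radius <- max_radius %||% (N * sqrt(2) / 2)
  stopifnot(max_radius > 0)
  num_radii <- as.integer(num_radii %||% (ceiling(N * sqrt(2) / 2) + 1))
  num_angles <- as.integer(num_angles %||%
                             next_smooth4(ceiling(2 * pi * max_radius)))
  stopifnot(num_angles >= 4, num_radii >= 2)
  center <- center %||% c((N + 1) / 2, (N + 1) / 2)
  structure(list(N = N, M = num_angles, K = num_radii,
                 center = center, max_radius = max_radius,
                 dr = max_radius / (num_radii - 1),
                 dphi = 2 * pi / num_angles,
                 radii = seq(0, max_radius, length.out = num_radii),
                 interp = interp,
                 cache = new.env(parent = emptyenv())),
            class = "polar_grid_spec")
}

#' @export
print.polar_grid_spec <- function(x, ...) {
  cat(sprintf("Polar grid: %d angles x %d radii, center (%.1f, %.1f), max radius %.2f px, %s interpolation\n",
              x$M, x$K, x$center[1], x$center[2], x$max_radius, x$interp))
  invisible(x)
}

# Smallest multiple of 4 at least n whose prime factors are all in
# {2, 3, 5}, so the angular FFTs use fast lengths.
next_smooth4 <- function(n) {
  n <- max(4L, as.integer(n))
  m <- n + (-n %% 4)
  repeat {
    k <- m
    for (p in c(2L, 3L, 5L)) while (k %% p == 0L) k <- k %/% p
    if (k == 1L) return(as.integer(m))
    m <- m + 4L
  }
}

# Interpolation kernel weights at signed distance t from a node.
interp_kernel <- function(t, interp) {
  at <- abs(t)
  if (interp == "bilinear") return(pmax(1 - at, 0))
  # Catmull-Rom (Keys, a = -1/2)
  ifelse(at <= 1, 1.5 * at^3 - 2.5 * at^2 + 1,
         ifelse(at < 2, -0.5 * at^3 + 2.5 * at^2 - 4 * at + 2, 0))
}

interp_taps <- function(interp) if (interp == "bilinear") 0:1 else -1:2

# Sparse gather matrix mapping an N^2 Cartesian vector to the M*K polar
# vector (angle-major).  Samples outside the image contribute zero.
polar_gather_matrix <- function(spec) {
  if (!is.null(spec$cache$Tmat)) return(spec$cache$Tmat)
  M <- spec$M; K <- spec$K; N <- spec$N
  phi <- (seq_len(M) - 1) * spec$dphi
  rr <- rep(spec$radii, each = M)
  ph <- rep(phi, K)
  rows <- spec$center[1] + rr * sin(ph)
  cols <- spec$center[2] + rr * cos(ph)
  r0 <- floor(rows); c0 <- floor(cols)
  taps <- interp_taps(spec$interp)
  ii <- jj <- xx <- list()
  s <- seq_len(M * K)
  k <- 0
  for (dr in taps) for (dc in taps) {
    ri <- r0 + dr; ci <- c0 + dc
    w <- interp_kernel(rows - ri, spec$interp) *
         interp_kernel(cols - ci, spec$interp)
    ok <- ri >= 1 & ri <= N & ci >= 1 & ci <= N & abs(w) > 1e-12
    k <- k + 1
    ii[[k]] <- s[ok]; jj[[k]] <- ri[ok] + (ci[ok] - 1) * N; xx[[k]] <- w[ok]
  }
  Tmat <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                               dims = c(M * K, N * N))
  spec$cache$Tmat <- Tmat
  Tmat
}

# Sparse gather matrix mapping the M*K polar vector back to the N^2
# Cartesian vector.  The angular axis wraps circularly; the radial axis
# is continued through the center (radius -r maps to radius r at angle
# phi + pi), and Cartesian pixels beyond max_radius are zero.
polar_scatter_matrix <- function(spec) {
  if (!is.null(spec$cache$Fmat)) return(spec$cache$Fmat)
  M <- spec$M; K <- spec$K; N <- spec$N
  rows <- matrix(seq_len(N), N, N) - spec$center[1]
  cols <- matrix(seq_len(N), N, N, byrow = TRUE) - spec$center[2]
  r <- sqrt(rows^2 + cols^2)
  ph <- atan2(rows, cols) %% (2 * pi)
  kf <- as.vector(r / spec$dr)          # fractional radial index (0-based)
  mf <- as.vector(ph / spec$dphi)       # fractional angular index (0-based)
  inside <- kf <= (K - 1) + 1e-9
  kf <- pmin(kf, K - 1)
  m0 <- floor(mf); k0 <- floor(kf)
  taps <- interp_taps(spec$interp)
  half_turn <- round(M / 2)
  ii <- jj <- xx <- list()
  s <- seq_len(N * N)
  q <- 0
  for (dm in taps) for (dk in taps) {
    mi <- (m0 + dm) %% M
    ki <- k0 + dk
    w <- interp_kernel(mf - (m0 + dm), spec$interp) *
         interp_kernel(kf - ki, spec$interp)
    neg <- ki < 0
    mi2 <- ifelse(neg, (mi + half_turn) %% M, mi)
    ki2 <- abs(ki)
    ok <- inside & ki2 <= K - 1 & abs(w) > 1e-12
    q <- q + 1
    ii[[q]] <- s[ok]; jj[[q]] <- mi2[ok] + 1 + ki2[ok] * M; xx[[q]] <- w[ok]
  }
  Fmat <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                               dims = c(N * N, M * K))
  spec$cache$Fmat <- Fmat
  Fmat
}

#' Cartesian to polar transform
#'
#' Resamples a square image onto the `(angle x radius)` grid of `spec` by
#' separable interpolation about the optical center.  Samples falling
#' outside the image are zero.
#'
#' @param image square numeric matrix.
#' @param spec a [polar_grid_spec] (default grid for `nrow(image)` if
#'   omitted).
#' @return a `polar_image`: `M x K` matrix (angle-major) with the spec
#'   attached as attribute `"spec"`.
#' @export
to_polar <- function(image, spec = polar_grid_spec(nrow(image))) {
  if (!is.matrix(image) || nrow(image) != ncol(image) || nrow(image) == 0)
    stop("image must be a non-empty square matrix")
  if (!all(is.finite(image))) stop("image must be finite")
  stopifnot(spec$N == nrow(image))
  v <- as.numeric(polar_gather_matrix(spec) %*% as.vector(image))
  structure(matrix(v, spec$M, spec$K), spec = spec, class = "polar_image")
}

#' Polar to Cartesian transform
#'
#' Inverse resampling of a polar-grid image onto the `N x N` Cartesian
#' grid: each Cartesian pixel gathers from the polar array at its own
#' `(radius, angle)` coordinates, with circular wrap along the angle
#' axis.
#'
#' @param pimg `M x K` polar array (a `polar_image` or plain matrix).
#' @param N output side length.
#' @param spec [polar_grid_spec]; taken from `pimg` when omitted.
#' @return `N x N` matrix.
#' @export
from_polar <- function(pimg, N = NULL, spec = attr(pimg, "spec")) {
  if (is.null(spec)) stop("no polar_grid_spec available")
  N <- N %||% spec$N
  if (N != spec$N) stop("output size does not match polar grid spec")
  if (nrow(pimg) != spec$M || ncol(pimg) != spec$K)
    stop("polar image shape does not match spec")
  matrix(as.numeric(polar_scatter_matrix(spec) %*% as.vector(pimg)), N, N)
}

# Exact adjoints of the two transforms (scatter with identical weights).
to_polar_adjoint <- function(pimg, spec) {
  matrix(as.numeric(Matrix::crossprod(polar_gather_matrix(spec), as.vector(pimg))),
         spec$N, spec$N)
}

from_polar_adjoint <- function(image, spec) {
  matrix(as.numeric(Matrix::crossprod(polar_scatter_matrix(spec), as.vector(image))),
         spec$M, spec$K)
}
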