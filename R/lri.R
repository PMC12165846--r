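# The linear revolution-invariant (LRI) forward model.  Under rotational
# symmetry the image of an object g is an integral over object radius of
# 1D circular convolutions along the angular coordinate ("ring
# convolution"), computable ring-by-ring with 1D FFTs in O(N^3 log N)
# instead of the O(N^4) brute-force superposition.

#' Ring convolution operator
#'
#' Precomputes everything needed to apply the LRI forward model and its
#' exact adjoint repeatedly: the polar transform operators, the
#' angular-spectrum bank of the PSF stack, radial quadrature weights and
#' (optionally) the flat-field normalization image.
#'
#' The radial quadrature weights are `w_j = r_j * dr` for `j >= 1` and
#' `w_0 = dr^2 / 8` (the area share of the central half-pixel disc per
#' angular sample); an angular factor `dphi` completes the polar area
#' element.  With `flat_field = TRUE` the output is divided by the
#' response to an all-ones object, cancelling residual radial quadrature
#' bias; this keeps the operator linear.
#'
#' @param h a [radial_psf_stack].
#' @param spec a [polar_grid_spec]; by default one whose radii coincide
#'   with the stack's.  If the radii differ, the polar-transformed stack
#'   is linearly interpolated onto the grid radii.
#' @param flat_field divide by the all-ones response (default `FALSE`;
#'   with energy-normalized PSF stacks the edge dimming of the flat
#'   response is physical vignetting and should not be divided out, but
#'   the option is useful with externally normalized kernel banks).
#' @param cache_limit maximum bytes of PSF angular spectra to keep
#'   resident; above it the spectra are recomputed per application
#'   (memory/speed trade-off, relevant only for large N).
#' @return an object of class `ring_operator` with elements
#'   `forward(g)` and `adjoint(f)` (both `N x N -> N x N`), plus the
#'   `spec`, `weights` and `flat` field.
#' @export
ring_operator <- function(h, spec = NULL, flat_field = FALSE,
                          cache_limit = 3e8) {
  stopifnot(inherits(h, "radial_psf_stack"))
  N <- h$image_N
  spec <- spec %||% polar_grid_spec(N, num_radii = length(h$radii),
                                    max_radius = max(h$radii))
  M <- spec$M; K <- spec$K
  # polar-transform the stack; the PSF canvas may be larger than the
  # image, so it gets its own gather operator on the same (M, K) grid
  Tmat <- polar_gather_matrix(spec)
  Fmat <- polar_scatter_matrix(spec)
  Tpsf <- if (h$N == N) Tmat else
    polar_gather_matrix(polar_grid_spec(h$N, num_angles = M, num_radii = K, interp = spec$interp,
                                        max_radius = spec$max_radius))
  radii_aligned <- length(h$radii) == K &&
    max(abs(h$radii - spec$radii)) < 1e-9
  # resample along radius if grid and stack radii differ
  pol_stack <- function() {
    ph <- lapply(h$psfs, function(p)
      matrix(as.numeric(Tpsf %*% as.vector(p)), M, K))
    if (radii_aligned)
      return(ph)
    lapply(spec$radii, function(r) {
      j <- findInterval(r, h$radii, all.inside = TRUE)
      t <- (r - h$radii[j]) / (h$radii[j + 1] - h$radii[j])
      t <- min(max(t, 0), 1)
      (1 - t) * ph[[j]] + t * ph[[j + 1]]
    })
  }
  # radial support of one PSF (ring indices), from its Cartesian
  # bounding box about the canvas center (conservative by one ring)
  psf_band <- function(p, thr) {
    nzr <- which(rowSums(p * p) > thr)
    nzc <- which(colSums(p * p) > thr)
    if (!length(nzr) || !length(nzc)) return(1L)
    ctr <- (h$N + 1) / 2
    dr <- range(nzr) - ctr
    dc <- range(nzc) - ctr
    r_hi <- sqrt(max(dr^2) + max(dc^2))
    r_lo <- if (prod(range(dr)) <= 0 && prod(range(dc)) <= 0) 0 else
      sqrt(min(abs(dr))^2 * (prod(range(dr)) > 0) +
           min(abs(dc))^2 * (prod(range(dc)) > 0))
    kk <- which(spec$radii >= r_lo - 2 * spec$dr &
                spec$radii <= r_hi + 2 * spec$dr)
    if (!length(kk)) 1L else min(kk):max(kk)
  }
  w <- spec$radii * spec$dr
  w[1] <- spec$dr^2 / 8
  w <- w * spec$dphi
  # The polar PSF matrix is band-limited in radius: the PSF of ring j
  # has no appreciable energy at output rings far from r_j, so only the
  # rings carrying the PSF's support are transformed and mixed.  The
  # truncation threshold is far below the interpolation error floor.
  use_cache <- (as.numeric(M) * K * K * 16) <= cache_limit
  make_Hhat <- function() {
    if (radii_aligned) {
      # feed only each PSF's support pixels through the gather operator
      # (column subsetting is cheap in compressed-column storage), then
      # keep the radial band its energy lands in
      gmax2 <- max(vapply(h$psfs, function(p) max(p * p), numeric(1)))
      thr <- 1e-26 * gmax2
      return(lapply(h$psfs, function(p) {
        nzr <- which(rowSums(p * p) > thr)
        nzc <- which(colSums(p * p) > thr)
        if (!length(nzr)) { nzr <- 1L; nzc <- 1L }
        rr <- min(nzr):max(nzr); cc <- min(nzc):max(nzc)
        idx <- as.vector(outer(rr, (cc - 1L) * h$N, "+"))
        pm <- matrix(as.numeric(Tpsf[, idx, drop = FALSE] %*%
                                  p[cbind(rep(rr, length(cc)),
                                          rep(cc, each = length(rr)))]),
                     M, K)
        band <- psf_band(p, thr)
        list(band = band,
             spec = stats::mvfft(pm[, band, drop = FALSE]))
      }))
    }
    ph <- pol_stack()
    gmax <- max(vapply(ph, function(p) max(abs(p)), numeric(1)))
    lapply(ph, function(p) {
      keep <- which(colSums(p * p) > (1e-13 * gmax)^2)
      if (!length(keep)) keep <- 1L
      keep <- min(keep):max(keep)
      list(band = keep, spec = stats::mvfft(p[, keep, drop = FALSE]))
    })
  }
  Hhat <- if (use_cache) make_Hhat() else NULL
  get_Hhat <- function() Hhat %||% make_Hhat()

  forward_raw <- function(g) {
    Ghat <- stats::mvfft(matrix(as.numeric(Tmat %*% as.vector(g)), M, K))
    HH <- get_Hhat()
    fhat <- matrix(0 + 0i, M, K)
    # f^(m, i) = sum_j w_j G^(m, j) H^(m, j, i)
    for (j in seq_len(K)) {
      b <- HH[[j]]$band
      fhat[, b] <- fhat[, b] + (w[j] * Ghat[, j]) * HH[[j]]$spec
    }
    fpol <- Re(stats::mvfft(fhat, inverse = TRUE)) / M
    matrix(as.numeric(Fmat %*% as.vector(fpol)), N, N)
  }
  adjoint_raw <- function(f) {
    apol <- matrix(as.numeric(Matrix::crossprod(Fmat, as.vector(f))), M, K)
    Ahat <- stats::mvfft(apol)
    HH <- get_Hhat()
    ghat <- matrix(0 + 0i, M, K)
    # g^(m, j) = w_j sum_i conj(H^(m, j, i)) A^(m, i)
    for (j in seq_len(K)) {
      b <- HH[[j]]$band
      ghat[, j] <- w[j] *
        rowSums(Conj(HH[[j]]$spec) * Ahat[, b, drop = FALSE])
    }
    gpol <- Re(stats::mvfft(ghat, inverse = TRUE)) / M
    matrix(as.numeric(Matrix::crossprod(Tmat, as.vector(gpol))), N, N)
  }

  flat <- NULL
  if (flat_field) {
    ff <- forward_raw(matrix(1, N, N))
    flat <- pmax(ff, 1e-8 * max(ff))
  }
  op <- list(
    spec = spec, weights = w, flat = flat, N = N,
    forward = function(g) {
      out <- forward_raw(g)
      if (!is.null(flat)) out <- out / flat
      out
    },
    adjoint = function(f) {
      if (!is.null(flat)) f <- f / flat
      adjoint_raw(f)
    })
  class(op) <- "ring_operator"
  op
}

check_image_stack <- function(g, h) {
  if (!is.matrix(g) || nrow(g) != ncol(g)) stop("g must be a square matrix")
  N <- if (inherits(h, "radial_psf_stack")) h$image_N else h$N
  if (nrow(g) != N) stop("image and PSF stack sizes differ")
}

#' Ring convolution (FFT form)
#'
#' Applies the exact LRI forward model: the object is resampled to polar
#' coordinates, each object ring is circularly convolved along the
#' angular axis with the corresponding ring of every PSF's polar
#' transform (1D FFTs), the rings are summed with radial quadrature
#' weights, and the result is resampled back to Cartesian coordinates.
#' Linear in `g`; cost `O(N^3 log N)`.
#'
#' @param g square object image.
#' @param h a [radial_psf_stack], or a prebuilt [ring_operator] (then
#'   `spec` and `flat_field` are ignored).
#' @param spec optional [polar_grid_spec].
#' @param flat_field see [ring_operator].
#' @return blurred `N x N` image.
#' @export
ring_convolve <- function(g, h, spec = NULL, flat_field = FALSE) {
  op <- if (inherits(h, "ring_operator")) h
        else ring_operator(h, spec, flat_field)
  check_image_stack(g, op)
  op$forward(g)
}

#' Adjoint of ring convolution
#'
#' Applies the exact adjoint of [ring_convolve] (the "ring correlation"),
#' satisfying `<ring_convolve(g), f> == <g, ring_correlate(f)>` to
#' numerical precision.  Needed for the data-fidelity gradient in ring
#' deconvolution.
#'
#' @inheritParams ring_convolve
#' @param f square image in the data domain.
#' @return `N x N` image in the object domain.
#' @export
ring_correlate <- function(f, h, spec = NULL, flat_field = FALSE) {
  op <- if (inherits(h, "ring_operator")) h
        else ring_operator(h, spec, flat_field)
  check_image_stack(f, op)
  op$adjoint(f)
}

#' Ring convolution (direct spatial-domain form)
#'
#' Same contract as [ring_convolve] but with the angular circular
#' convolutions evaluated as explicit spatial-domain sums rather than via
#' the FFT.  Serves as the internal equivalence oracle for the FFT form
#' (the two agree to numerical precision on the identical
#' discretization).
#'
#' @inheritParams ring_convolve
#' @return blurred `N x N` image.
#' @export
ring_convolve_direct <- function(g, h, spec = NULL, flat_field = FALSE) {
  stopifnot(inherits(h, "radial_psf_stack"))
  N <- h$image_N
  check_image_stack(g, h)
  spec <- spec %||% polar_grid_spec(N, num_radii = length(h$radii),
                                    max_radius = max(h$radii))
  M <- spec$M; K <- spec$K
  Tmat <- polar_gather_matrix(spec)
  Fmat <- polar_scatter_matrix(spec)
  Tpsf <- if (h$N == N) Tmat else
    polar_gather_matrix(polar_grid_spec(h$N, num_angles = M, num_radii = K, interp = spec$interp,
                                        max_radius = spec$max_radius))
  if (length(h$radii) != K || max(abs(h$radii - spec$radii)) > 1e-9)
    stop("direct form requires stack radii matching the polar grid")
  w <- spec$radii * spec$dr
  w[1] <- spec$dr^2 / 8
  w <- w * spec$dphi
  gpol <- matrix(as.numeric(Tmat %*% as.vector(g)), M, K)
  # index matrix for circular convolution: row i, col m -> (i - m) mod M
  IM <- (outer(0:(M - 1), 0:(M - 1), "-") %% M) + 1L
  fpol <- matrix(0, M, K)
  for (j in seq_len(K)) {
    hp <- matrix(as.numeric(Tpsf %*% as.vector(h$psfs[[j]])), M, K)
    a <- w[j] * gpol[, j]
    # f[, i] += sum_m a[m] * hp[(i - m) mod M, i] for every output ring i
    for (i in seq_len(K)) {
      fpol[, i] <- fpol[, i] + as.vector(matrix(hp[IM, i], M, M) %*% a)
    }
  }
  out <- matrix(as.numeric(Fmat %*% as.vector(fpol)), N, N)
  if (flat_field) {
    ff <- ring_convolve_direct(matrix(1, N, N), h, spec, flat_field = FALSE)
    out <- out / pmax(ff, 1e-8 * max(ff))
  }
  out
}

#' Brute-force spatially varying blur ("true blur")
#'
#' Discretizes the superposition integral directly: every object pixel
#' contributes its own field-position-dependent PSF, weighted by the
#' pixel value.  Exact but `O(N^4)`; used as the ground-truth oracle
#' against which ring convolution and standard convolution are compared.
#'
#' @param g square object image.
#' @param coeffs [seidel_coefficients] used to render the per-pixel PSFs
#'   (ignored when `psf_fun` is given).
#' @param grid an [optical_grid] matching `g`.
#' @param psf_fun optional generator `function(r, theta)` returning the
#'   `N x N` PSF of a source at that polar position.
#' @return blurred `N x N` image.
#' @export
true_blur <- function(g, coeffs = NULL, grid = NULL, psf_fun = NULL) {
  if (!is.matrix(g) || nrow(g) != ncol(g)) stop("g must be a square matrix")
  N <- nrow(g)
  ctr <- (N + 1) / 2
  f <- matrix(0, N, N)
  if (is.null(psf_fun)) {
    # lean inline renderer: identical math to render_psf (energy
    # normalization), with the crop indices and pupil basis hoisted out
    # of the N^2-iteration loop
    stopifnot(inherits(grid, "optical_grid"), grid$N == N)
    w <- unclass(as_seidel(coeffs))
    L <- grid$pupil_samples
    b <- pupil_basis(L, grid$pupil_fill)
    # positions of the fftshifted crop window in unshifted coordinates
    off <- floor((L - N) / 2)
    cpad <- floor(L / 2) + 1
    crop_idx <- ((off + seq_len(N) - 1 + ceiling(L / 2)) %% L) + 1
    energy <- as.numeric(L)^2 * length(b$idx)
    Pm <- matrix(0 + 0i, L, L)
    base_shift <- off + (N + 1) / 2 - cpad
    for (jc in seq_len(N)) {
      dx <- jc - ctr
      for (ir in seq_len(N)) {
        v <- g[ir, jc]
        if (v == 0) next
        dy <- ir - ctr
        r <- sqrt(dx^2 + dy^2)
        H <- r / grid$r_max
        if (H > 1) stop("source radius exceeds r_max (out of field)")
        th <- atan2(dy, dx)
        cpsi <- cos(th) * b$X + sin(th) * b$Y
        W <- w[1] * b$rho4 + w[2] * H * b$rho2 * cpsi +
             w[3] * H^2 * cpsi^2 + w[4] * H^2 * b$rho2 + w[5] * H^3 * cpsi
        ramp <- ((base_shift + dy) * b$my + (base_shift + dx) * b$mx) / L
        Pm[b$idx] <- exp(2i * pi * (W + ramp))
        a <- fft2(Pm)
        int <- Re(a)^2 + Im(a)^2
        f <- f + (v / energy) * int[crop_idx, crop_idx]
      }
    }
    return(f)
  }
  for (jc in seq_len(N)) {
    dx <- jc - ctr
    for (ir in seq_len(N)) {
      v <- g[ir, jc]
      if (v == 0) next
      dy <- ir - ctr
      f <- f + v * psf_fun(sqrt(dx^2 + dy^2), atan2(dy, dx))
    }
  }
  f
}

#' Space-invariant (standard) convolution with a centered PSF
#'
#' Circular FFT convolution of an image with a single PSF whose center is
#' at the optical center `((N+1)/2, (N+1)/2)`.  This is the classical LSI
#' forward model used as the comparison baseline.
#'
#' @param g square image.
#' @param psf square PSF of the same size, centered at the optical
#'   center.
#' @param correlate if `TRUE` apply the adjoint (correlation) instead.
#' @return `N x N` image.
#' @export
lsi_convolve <- function(g, psf, correlate = FALSE) {
  stopifnot(all(dim(g) == dim(psf)))
  n <- nrow(g)
  conv2_centered(g, psf, center = c((n + 1) / 2, (n + 1) / 2),
                 correlate = correlate)
}
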