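# Lateral-symmetry analogue of ring convolution for light-sheet
# microscopy: the detection optics are space-invariant but the
# illumination sheet thickens away from its waist, so the 3D PSF varies
# along one axis (u) only.  The forward model is then an integral over u
# of 2D convolutions in the invariant (v, t) plane.

#' Light-sheet PSF model
#'
#' Parameterizes the spatially varying 3D PSF of a light-sheet
#' microscope as a space-invariant detection PSF multiplied by a
#' Gaussian axial envelope whose spread follows the Gaussian-beam
#' profile \eqn{\sigma(u) = \alpha\sqrt{1 + (\beta u)^2}}: `alpha` is
#' the axial spread at the sheet waist and `beta` the rate at which it
#' grows along the sheet-focus axis `u`.
#'
#' @param alpha waist axial spread, voxels (> 0).
#' @param beta spread growth rate, 1/voxel (>= 0).
#' @param base_psf the detection (imaging) PSF: a 3D array with odd
#'   dimensions, or `NULL` to use a scalar-diffraction defocus model
#'   built by [make_base_psf_3d].
#' @param base_dims dimensions for the default base PSF.
#' @return object of class `lsfm_psf_model`.
#' @export
lsfm_psf_model <- function(alpha, beta, base_psf = NULL,
                           base_dims = c(9, 9, 17)) {
  stopifnot(alpha > 0, beta >= 0)
  base_psf <- base_psf %||% make_base_psf_3d(base_dims)
  stopifnot(length(dim(base_psf)) == 3, all(dim(base_psf) %% 2 == 1))
  structure(list(alpha = alpha, beta = beta, base_psf = base_psf),
            class = "lsfm_psf_model")
}

#' @export
print.lsfm_psf_model <- function(x, ...) {
  cat(sprintf("LSFM PSF model: alpha = %.3f vx, beta = %.4f /vx, base PSF %s\n",
              x$alpha, x$beta, paste(dim(x$base_psf), collapse = "x")))
  invisible(x)
}

#' Scalar-diffraction defocus detection PSF
#'
#' Builds a simple space-invariant 3D detection PSF: each axial slice is
#' the intensity of a circular pupil with a defocus phase proportional
#' to the axial offset.  This stands in for a full optical-path-
#' difference PSF model; any measured or externally computed 3D PSF can
#' be supplied to [lsfm_psf_model] instead.  The default defocus rate
#' gives a detection depth of field longer than typical sheet
#' thicknesses, the regime where light-sheet optical sectioning (and
#' axial-resolution recovery) is meaningful.
#'
#' @param dims odd `(x, y, z)` dimensions.
#' @param defocus_scale defocus in waves per voxel of axial offset.
#' @param fill pupil fill fraction (see [optical_grid]).
#' @return 3D array, unit sum.
#' @export
make_base_psf_3d <- function(dims = c(9, 9, 17), defocus_scale = 0.08,
                             fill = 0.5) {
  stopifnot(all(dims %% 2 == 1))
  L <- 2 * max(dims[1:2]) + 2
  b <- pupil_basis(L, fill)
  cz <- (dims[3] + 1) / 2
  cpad <- floor(L / 2) + 1
  h <- (dims[1:2] - 1) / 2
  psf <- array(0, dims)
  for (iz in seq_len(dims[3])) {
    w20 <- defocus_scale * (iz - cz)
    P <- matrix(0 + 0i, L, L)
    P[b$idx] <- exp(2i * pi * w20 * b$rho2)
    a <- fftshift2(abs(fft2(P))^2)
    psf[, , iz] <- a[cpad + (-h[1]:h[1]), cpad + (-h[2]:h[2])]
  }
  psf / sum(psf)
}

#' Axial spread of the light sheet
#'
#' Evaluates the Gaussian-beam spread profile
#' \eqn{\sigma(u) = \alpha\sqrt{1+(\beta u)^2}}.
#'
#' @param model an [lsfm_psf_model].
#' @param u sheet-focus coordinate relative to the waist (voxels; may be
#'   a vector).
#' @return spread in voxels.
#' @export
sigma_profile <- function(model, u) {
  stopifnot(inherits(model, "lsfm_psf_model"))
  model$alpha * sqrt(1 + (model$beta * u)^2)
}

#' Light-sheet PSF at a sheet-focus position
#'
#' The detection PSF multiplied along its axial (z) coordinate by the
#' normalized Gaussian sheet profile
#' \eqn{\exp(-z^2/2\sigma(u)^2)/(\sigma(u)\sqrt{2\pi})}.  The product is
#' deliberately *not* renormalized: a thicker sheet spreads the same
#' weight over the fixed detection-PSF support, so total flux decreases
#' away from the waist, as it does physically.
#'
#' @param model an [lsfm_psf_model].
#' @param u sheet-focus coordinate relative to the waist (voxels).
#' @return 3D PSF array with the dimensions of the base PSF.
#' @export
lsfm_psf <- function(model, u) {
  s <- sigma_profile(model, u)
  if (s <= 0) stop("sheet spread must be positive")
  d <- dim(model$base_psf)
  cz <- (d[3] + 1) / 2
  env <- exp(-0.5 * ((seq_len(d[3]) - cz) / s)^2) / (s * sqrt(2 * pi))
  sweep(model$base_psf, 3, env, `*`)
}

#' Interpolate a measured PSF set at an arbitrary sheet position
#'
#' Convex combination of the two measured PSFs bracketing `u_query`;
#' outside the measured range the nearest endpoint PSF is returned
#' (documented clamp).
#'
#' @param u_query sheet-focus coordinate.
#' @param set list with `psfs` (list of 3D arrays) and `u_positions`
#'   (strictly increasing).
#' @return 3D PSF array.
#' @export
interpolate_psf <- function(u_query, set) {
  stopifnot(length(set$psfs) >= 1,
            length(set$psfs) == length(set$u_positions))
  u <- set$u_positions
  if (u_query <= u[1]) return(set$psfs[[1]])
  if (u_query >= u[length(u)]) return(set$psfs[[length(u)]])
  j <- findInterval(u_query, u)
  t <- (u_query - u[j]) / (u[j + 1] - u[j])
  (1 - t) * set$psfs[[j]] + t * set$psfs[[j + 1]]
}

#' Axial PSF set
#'
#' Container for 3D PSFs measured (or generated) along the sheet-focus
#' axis.
#'
#' @param psfs list of 3D arrays with identical odd dimensions.
#' @param u_positions strictly increasing sheet-focus coordinates.
#' @return object of class `axial_psf_set`.
#' @export
axial_psf_set <- function(psfs, u_positions) {
  stopifnot(length(psfs) == length(u_positions),
            all(diff(u_positions) > 0))
  structure(list(psfs = psfs, u_positions = as.numeric(u_positions)),
            class = "axial_psf_set")
}

# Resolve a per-slice PSF list for a volume with Nu slices: one 3D PSF
# per slice index, from either a parametric model (waist at the volume
# center) or an interpolated measured set.
slice_psfs <- function(psfs, Nu) {
  if (inherits(psfs, "lsfm_psf_model")) {
    u0 <- (Nu + 1) / 2
    lapply(seq_len(Nu), function(iu) lsfm_psf(psfs, iu - u0))
  } else if (inherits(psfs, "axial_psf_set")) {
    lapply(seq_len(Nu), function(iu) interpolate_psf(iu, psfs))
  } else stop("psfs must be an lsfm_psf_model or axial_psf_set")
}

# Centrally crop a 3D PSF so each (odd) dimension fits in the volume.
crop_psf_to <- function(p, dims) {
  dp <- dim(p)
  tgt <- pmin(dp, dims - (1 - dims %% 2))   # keep odd sizes
  tgt <- tgt - (1 - tgt %% 2)
  if (all(tgt == dp)) return(p)
  h <- (tgt - 1) %/% 2
  c0 <- (dp + 1) %/% 2
  p[(c0[1] - h[1]):(c0[1] + h[1]),
    (c0[2] - h[2]):(c0[2] + h[2]),
    (c0[3] - h[3]):(c0[3] + h[3]), drop = FALSE]
}

# Operator factory for sheet convolution and its exact adjoint on
# volumes of dimension dims = (Nu, Nv, Nt).  2D convolutions over (v, t)
# are circular (FFT); the u axis is summed directly with boundary
# clipping.
sheet_operator <- function(psfs, dims) {
  Nu <- dims[1]; Nv <- dims[2]; Nt <- dims[3]
  pl <- slice_psfs(psfs, Nu)
  pl <- lapply(pl, crop_psf_to, dims = dims)
  dp <- dim(pl[[1]])
  hx <- (dp[1] - 1) %/% 2
  cyz <- (dp[2:3] + 1) / 2
  # precompute FFTs of every (v,t) sheet of every slice PSF, kernel
  # center moved to (1,1)
  ky <- freq_index(Nv) / Nv; kz <- freq_index(Nt) / Nt
  ramp <- exp(2i * pi * outer(ky * (cyz[1] - 1), kz * (cyz[2] - 1), "+"))
  Hf <- lapply(pl, function(p) {
    lapply(seq_len(dp[1]), function(ix) {
      emb <- matrix(0, Nv, Nt)
      emb[seq_len(dp[2]), seq_len(dp[3])] <- p[ix, , ]
      fft2(emb) * ramp
    })
  })
  forward <- function(g) {
    stopifnot(all(dim(g) == dims))
    Fh <- vector("list", Nu)
    for (ix in seq_len(Nu)) Fh[[ix]] <- matrix(0 + 0i, Nv, Nt)
    for (iu in seq_len(Nu)) {
      Gh <- fft2(g[iu, , ])
      for (ix in seq_len(dp[1])) {
        ox <- iu + ix - 1 - hx
        if (ox < 1 || ox > Nu) next
        Fh[[ox]] <- Fh[[ox]] + Gh * Hf[[iu]][[ix]]
      }
    }
    f <- array(0, dims)
    for (ix in seq_len(Nu)) f[ix, , ] <- Re(ifft2(Fh[[ix]]))
    f
  }
  adjoint <- function(f) {
    stopifnot(all(dim(f) == dims))
    Fh <- lapply(seq_len(Nu), function(ix) fft2(f[ix, , ]))
    g <- array(0, dims)
    for (iu in seq_len(Nu)) {
      Ah <- matrix(0 + 0i, Nv, Nt)
      for (ix in seq_len(dp[1])) {
        ox <- iu + ix - 1 - hx
        if (ox < 1 || ox > Nu) next
        Ah <- Ah + Conj(Hf[[iu]][[ix]]) * Fh[[ox]]
      }
      g[iu, , ] <- Re(ifft2(Ah))
    }
    g
  }
  list(forward = forward, adjoint = adjoint, psf_dims = dp)
}

#' Sheet convolution
#'
#' Exact forward model for a system whose 3D PSF varies along one axis
#' (`u`, the sheet-focus axis, the first array dimension) only: the
#' output is the sum over source slices of 2D circular convolutions of
#' each slice with the corresponding sheets of that slice's PSF.  Cost
#' `O(N^4 log N)` versus `O(N^6)` for unrestricted spatially varying 3D
#' blur.
#'
#' @param g 3D volume `(Nu, Nv, Nt)`.
#' @param psfs an [lsfm_psf_model] (waist at the volume center) or an
#'   [axial_psf_set] interpolated per slice.
#' @return blurred volume, same dimensions.
#' @export
sheet_convolve <- function(g, psfs) {
  sheet_operator(psfs, dim(g))$forward(g)
}

#' Brute-force spatially varying 3D blur
#'
#' Places the full 3D PSF of every nonzero voxel, weighted by the voxel
#' value, with the same discretization as [sheet_convolve] (circular in
#' `(v, t)`, clipped along `u`).  `O(N^6)`; equivalence oracle only.
#'
#' @param g 3D volume.
#' @param psfs as in [sheet_convolve].
#' @return blurred volume.
#' @export
sheet_blur_direct <- function(g, psfs) {
  dims <- dim(g)
  Nu <- dims[1]; Nv <- dims[2]; Nt <- dims[3]
  pl <- slice_psfs(psfs, Nu)
  pl <- lapply(pl, crop_psf_to, dims = dims)
  dp <- dim(pl[[1]])
  h <- (dp - 1) %/% 2
  f <- array(0, dims)
  nz <- which(g != 0, arr.ind = TRUE)
  for (q in seq_len(nrow(nz))) {
    iu <- nz[q, 1]; iv <- nz[q, 2]; it <- nz[q, 3]
    val <- g[iu, iv, it]
    p <- pl[[iu]]
    for (ix in seq_len(dp[1])) {
      ox <- iu + ix - 1 - h[1]
      if (ox < 1 || ox > Nu) next
      vi <- ((iv + (seq_len(dp[2]) - 1 - h[2]) - 1) %% Nv) + 1
      ti <- ((it + (seq_len(dp[3]) - 1 - h[3]) - 1) %% Nt) + 1
      f[ox, vi, ti] <- f[ox, vi, ti] + val * p[ix, , ]
    }
  }
  f
}

#' Sheet deconvolution
#'
#' TV-regularized least-squares inversion of [sheet_convolve], solved
#' with the same adaptive-moment scheme as [ring_deconvolve], using the
#' exact adjoint of the sheet operator for the fidelity gradient.
#'
#' @param f blurred volume.
#' @param psfs as in [sheet_convolve].
#' @param cfg a [solver_config].
#' @param init optional initial estimate (default `f`).
#' @return a `deblur_result` whose estimate is a volume.
#' @export
sheet_deconvolve <- function(f, psfs, cfg = solver_config(), init = NULL) {
  op <- sheet_operator(psfs, dim(f))
  adam_least_squares(f, op$forward, op$adjoint, init %||% f, cfg)
}

#' Standard (space-invariant) 3D deconvolution
#'
#' The LSI baseline: iterative least squares with a single 3D PSF
#' applied by circular FFT convolution on all three axes.
#'
#' @param f blurred volume.
#' @param psf 3D PSF with odd dimensions (typically the waist PSF).
#' @param cfg a [solver_config].
#' @return a `deblur_result`.
#' @export
lsi_deconvolve_3d <- function(f, psf, cfg = solver_config()) {
  dims <- dim(f)
  emb <- array(0, dims)
  dp <- dim(psf)
  emb[seq_len(dp[1]), seq_len(dp[2]), seq_len(dp[3])] <- psf
  ctr <- (dp + 1) / 2
  kx <- freq_index(dims[1]) / dims[1]
  ky <- freq_index(dims[2]) / dims[2]
  kz <- freq_index(dims[3]) / dims[3]
  ph <- outer(kx * (ctr[1] - 1), outer(ky * (ctr[2] - 1), kz * (ctr[3] - 1), "+"), "+")
  Hh <- fft(emb) * exp(2i * pi * ph)
  fwd <- function(x) Re(fft(fft(x) * Hh, inverse = TRUE)) / length(x)
  adj <- function(x) Re(fft(fft(x) * Conj(Hh), inverse = TRUE)) / length(x)
  adam_least_squares(f, fwd, adj, f, cfg)
}

#' Fit the light-sheet PSF model to a bead calibration volume
#'
#' Detects isolated beads, crops a PSF-sized window around each, and
#' optimizes `(alpha, beta)` so the model PSFs at the beads' sheet-focus
#' positions match the measured crops in least squares, with per-bead
#' amplitude and background solved in closed form (box-constrained
#' quasi-Newton optimization).
#'
#' @param cal_stack 3D calibration volume of sparse beads.
#' @param base_psf detection PSF passed to [lsfm_psf_model].
#' @param base_dims dimensions of the default detection PSF.
#' @param u0 waist position along the first axis (default: volume
#'   center).
#' @param init initial `c(alpha, beta)`.
#' @param threshold_sigmas,min_separation bead detection parameters.
#' @return fitted [lsfm_psf_model], with the bead table in attribute
#'   `"beads"`.
#' @export
fit_lsfm_model <- function(cal_stack, base_psf = NULL,
                           base_dims = c(9, 9, 17), u0 = NULL,
                           init = c(alpha = 2, beta = 0.1),
                           threshold_sigmas = 5, min_separation = 12) {
  dims <- dim(cal_stack)
  u0 <- u0 %||% ((dims[1] + 1) / 2)
  beads <- detect_beads_3d(cal_stack, threshold_sigmas, min_separation)
  if (!nrow(beads)) stop("no beads detected in calibration stack")
  proto <- lsfm_psf_model(init[1], max(init[2], 0), base_psf, base_dims)
  dp <- dim(proto$base_psf)
  h <- (dp - 1) %/% 2
  # crops may be clipped by the volume boundary; the model PSF is then
  # compared on the same clipped subregion
  crops <- list(); us <- numeric(0); sub <- list()
  for (b in seq_len(nrow(beads))) {
    at <- as.numeric(beads[b, c("u", "v", "t")])
    lo <- pmax(at - h, 1); hi <- pmin(at + h, dims)
    if (any(hi - lo < h)) next   # keep at least half the window
    crops[[length(crops) + 1]] <-
      cal_stack[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
    sub[[length(sub) + 1]] <- cbind(lo - (at - h) + 1, dp - ((at + h) - hi))
    us <- c(us, at[1] - u0)
  }
  if (!length(crops)) stop("all detected beads are too close to the volume edge")
  energy <- sum(vapply(crops, function(c_) sum(c_^2), numeric(1)))
  obj <- function(par) {
    m <- lsfm_psf_model(par[1], par[2], proto$base_psf)
    loss <- 0
    for (k in seq_along(crops)) {
      s <- sub[[k]]
      mod <- lsfm_psf(m, us[k])[s[1, 1]:s[1, 2], s[2, 1]:s[2, 2],
                                s[3, 1]:s[3, 2]]
      mm <- mean(mod); mc <- mean(crops[[k]])
      va <- sum((mod - mm)^2)
      a <- if (va > 0) sum((mod - mm) * (crops[[k]] - mc)) / va else 0
      b0 <- mc - a * mm
      loss <- loss + sum((a * mod + b0 - crops[[k]])^2)
    }
    loss / energy
  }
  fit <- stats::optim(init, obj, method = "L-BFGS-B",
                      lower = c(0.2, 0), upper = c(20, 2),
                      control = list(factr = 1e3))
  out <- lsfm_psf_model(fit$par[1], fit$par[2], proto$base_psf)
  attr(out, "beads") <- beads
  out
}

# 3D local-maximum bead detection (integer voxel accuracy).
detect_beads_3d <- function(vol, threshold_sigmas = 5, min_separation = 12,
                            min_contrast = 0.02) {
  bg <- stats::median(vol)
  sig <- stats::mad(vol)
  thr <- bg + max(threshold_sigmas * sig, min_contrast * (max(vol) - bg),
                  1e-12)
  d <- dim(vol)
  cand <- which(vol > thr, arr.ind = TRUE)
  ok <- logical(nrow(cand))
  for (q in seq_len(nrow(cand))) {
    a <- cand[q, ]
    if (any(a == 1) || any(a == d)) next
    nb <- vol[(a[1] - 1):(a[1] + 1), (a[2] - 1):(a[2] + 1), (a[3] - 1):(a[3] + 1)]
    ok[q] <- vol[a[1], a[2], a[3]] >= max(nb)
  }
  cand <- cand[ok, , drop = FALSE]
  if (!nrow(cand))
    return(data.frame(u = numeric(0), v = numeric(0), t = numeric(0)))
  vals <- vol[cand]
  ord <- order(vals, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  for (q in seq_len(nrow(cand))) {
    if (!any(keep)) { keep[q] <- TRUE; next }
    dd <- sqrt(rowSums((cand[keep, , drop = FALSE] -
                          matrix(cand[q, ], sum(keep), 3, byrow = TRUE))^2))
    if (all(dd >= min_separation)) keep[q] <- TRUE
  }
  out <- as.data.frame(cand[keep, , drop = FALSE])
  names(out) <- c("u", "v", "t")
  out
}

#' Full width at half maximum along an axis
#'
#' Extracts the 1D profile through a peak along the given axis and
#' measures the width between the two half-maximum crossings, located
#' by linear interpolation.
#'
#' @param volume 3D array.
#' @param locations matrix or data.frame of voxel positions (rows:
#'   `u`, `v`, `t`).
#' @param axis 1 (u), 2 (v) or 3 (t).
#' @return numeric vector of FWHM values (voxels); `NA` with a warning
#'   where a crossing is not bracketed (peak at the volume edge).
#' @export
measure_fwhm <- function(volume, locations, axis = 3) {
  locations <- as.matrix(locations)[, 1:3, drop = FALSE]
  apply(locations, 1, function(at) {
    at <- round(as.numeric(at))
    prof <- switch(axis,
                   volume[, at[2], at[3]],
                   volume[at[1], , at[3]],
                   volume[at[1], at[2], ])
    p0 <- at[axis]
    # refine to the local max along the profile near the stated location
    lo <- max(1, p0 - 2); hi <- min(length(prof), p0 + 2)
    p0 <- (lo:hi)[which.max(prof[lo:hi])]
    half <- prof[p0] / 2
    li <- p0
    while (li > 1 && prof[li] > half) li <- li - 1
    ri <- p0
    while (ri < length(prof) && prof[ri] > half) ri <- ri + 1
    if (prof[li] > half || prof[ri] > half) {
      warning("half-maximum crossing not bracketed (peak at volume edge)")
      return(NA_real_)
    }
    left <- li + (half - prof[li]) / (prof[li + 1] - prof[li])
    right <- ri - (half - prof[ri]) / (prof[ri - 1] - prof[ri])
    right - left
  })
}
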