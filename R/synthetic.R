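# Seeded synthetic-data generators: coefficient samplers, procedural
# test objects, calibration-bead images, noise injection, blurred-image
# datasets and 3D bead volumes.  Every generator is a pure function of
# its arguments including the seed.

#' Noise specification
#'
#' @param kind `"gaussian"` (additive, variance set from `snr_db`),
#'   `"poisson"` (shot noise at `photon_scale` expected counts per unit
#'   intensity) or `"none"`.
#' @param snr_db target signal-to-noise ratio in dB, defined as
#'   `10*log10(mean signal power / noise variance)`; -20 dB means the
#'   noise power is 100 times the mean signal power.
#' @param photon_scale expected photon count for a pixel of intensity 1.
#' @param seed integer seed.
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(kind = c("none", "gaussian", "poisson"),
                       snr_db = 20, photon_scale = 1e4, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(is.finite(snr_db), photon_scale > 0)
  structure(list(kind = kind, snr_db = snr_db,
                 photon_scale = photon_scale, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Apply noise to an image or volume
#'
#' @param x numeric array (nonnegative for Poisson noise).
#' @param noise a [noise_spec]; `kind = "none"` returns `x` unchanged.
#' @return array of the same shape.
#' @export
add_noise <- function(x, noise) {
  stopifnot(inherits(noise, "noise_spec"))
  if (noise$kind == "none") return(x)
  if (noise$kind == "gaussian") {
    sigma <- sqrt(mean(x^2) / 10^(noise$snr_db / 10))
    return(with_seed(noise$seed,
                     x + array(stats::rnorm(length(x), sd = sigma),
                               dim(x) %||% length(x))))
  }
  if (any(x < 0)) stop("Poisson noise requires nonnegative input")
  with_seed(noise$seed,
            array(stats::rpois(length(x), noise$photon_scale * x) /
                    noise$photon_scale,
                  dim(x) %||% length(x)))
}

#' Sample random Seidel coefficient sets
#'
#' Draws aberration coefficient vectors covering systems from perfect to
#' highly aberrated: each coefficient i.i.d. uniform over `range`
#' (default 0-3 waves), or, in `"perturbed_grid"` mode, snapped to a
#' uniform grid and jittered by 10\% of the grid spacing.
#'
#' @param n number of coefficient sets.
#' @param mode `"uniform"` or `"perturbed_grid"`.
#' @param range coefficient range in waves.
#' @param seed integer seed.
#' @param grid_levels grid points per coefficient in perturbed-grid
#'   mode.
#' @return list of [seidel_coefficients].
#' @export
sample_seidel_coefficients <- function(n, mode = c("uniform", "perturbed_grid"),
                                       range = c(0, 3), seed = 1L,
                                       grid_levels = 4L) {
  mode <- match.arg(mode)
  stopifnot(n >= 1, range[1] >= 0, range[2] >= range[1])
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      if (mode == "uniform") {
        v <- stats::runif(5, range[1], range[2])
      } else {
        lv <- seq(range[1], range[2], length.out = grid_levels)
        sp <- if (grid_levels > 1) lv[2] - lv[1] else diff(range)
        v <- sample(lv, 5, replace = TRUE) +
          stats::runif(5, -0.1 * sp, 0.1 * sp)
        v <- pmin(pmax(v, range[1]), range[2])
      }
      as_seidel(v)
    })
  })
}

#' Procedural test image
#'
#' Generates a normalized `[0, 1]` test object as a mixture of smooth
#' filaments (random walks), soft discs and point scatterers --
#' structures typical of fluorescence microscopy scenes -- so that
#' validation needs no external image data.
#'
#' @param N side length.
#' @param seed integer seed.
#' @param n_filaments,n_discs,n_points component counts.
#' @param margin keep-out border in pixels.
#' @return `N x N` matrix in `[0, 1]`.
#' @export
make_test_image <- function(N, seed = 1L, n_filaments = 3, n_discs = 4,
                            n_points = 6, margin = 3) {
  with_seed(seed, {
    img <- matrix(0, N, N)
    rr <- function(lo, hi) stats::runif(1, lo, hi)
    for (i in seq_len(n_discs)) {
      r0 <- rr(margin + 2, N - margin - 1); c0 <- rr(margin + 2, N - margin - 1)
      s <- rr(1.5, N / 10)
      img <- img + rr(0.3, 1) *
        outer(1:N, 1:N, function(r, c) exp(-((r - r0)^2 + (c - c0)^2) / (2 * s^2)))
    }
    for (i in seq_len(n_filaments)) {
      p <- c(rr(margin, N - margin), rr(margin, N - margin))
      dir <- stats::runif(1, 0, 2 * pi)
      amp <- rr(0.4, 1)
      for (step in seq_len(3 * N)) {
        dir <- dir + stats::rnorm(1, 0, 0.25)
        p <- p + c(sin(dir), cos(dir))
        if (any(p < margin) || any(p > N - margin + 1)) break
        i0 <- floor(p)
        fr <- p - i0
        for (dr in 0:1) for (dc in 0:1) {
          w <- (if (dr == 0) 1 - fr[1] else fr[1]) *
               (if (dc == 0) 1 - fr[2] else fr[2])
          img[i0[1] + dr, i0[2] + dc] <- img[i0[1] + dr, i0[2] + dc] + amp * w
        }
      }
    }
    for (i in seq_len(n_points)) {
      img[sample(margin:(N - margin), 1), sample(margin:(N - margin), 1)] <-
        rr(0.5, 1.5) * max(img, 1)
    }
    # soften slightly so the object is resolvable at the simulated scale
    k <- outer(-2:2, -2:2, function(a, b) exp(-(a^2 + b^2) / 2))
    img <- conv2_centered(img, k_embed(k, N), center = c(3, 3) + (N - 5) / 2 + 1)
    img[img < 0] <- 0
    img / max(img)
  })
}

# embed a small kernel into an N x N zero matrix (centered)
k_embed <- function(k, N) {
  out <- matrix(0, N, N)
  h <- (nrow(k) - 1) / 2
  ctr <- floor(N / 2) + 1
  out[ctr + (-h:h), ctr + (-h:h)] <- k
  out
}

#' Synthetic calibration image of scattered point sources
#'
#' Places `J` point sources uniformly in the field of view (rejection
#' sampling under a minimum-separation constraint), renders each with
#' [render_psf] at its polar position, scales by a random amplitude in
#' `[0.5, 1]`, sums, and applies noise last.  Returns both the
#' ready-to-fit [calibration_image] (with ground-truth *nominal*
#' positions) and the truth table including each source's apparent peak
#' location.
#'
#' @param coeffs [seidel_coefficients] of the simulated system.
#' @param J number of sources.
#' @param grid an [optical_grid].
#' @param noise a [noise_spec].
#' @param min_separation minimum pairwise distance (pixels).
#' @param seed integer seed.
#' @param margin keep-out border in pixels (sources are nominally placed
#'   at least this far from the image edge).
#' @return list with `cal` (a [calibration_image] whose `sources` are
#'   the nominal truth), `truth` (data.frame: nominal `row`, `col`,
#'   `radius`, `theta`, `amplitude`, apparent `peak_row`, `peak_col`)
#'   and `image_clean` (the noiseless image).
#' @export
make_calibration_image <- function(coeffs, J, grid,
                                   noise = noise_spec("none"),
                                   min_separation = 10, seed = 1L,
                                   margin = 8) {
  stopifnot(J >= 1, inherits(grid, "optical_grid"))
  N <- grid$N
  ctr <- (N + 1) / 2
  with_seed(seed, {
    pos <- matrix(0, 0, 2)
    tries <- 0
    while (nrow(pos) < J) {
      cand <- stats::runif(2, margin, N - margin + 1)
      if (nrow(pos) == 0 ||
          all(sqrt(colSums((t(pos) - cand)^2)) >= min_separation)) {
        pos <- rbind(pos, cand)
      }
      tries <- tries + 1
      if (tries > 1e4)
        stop("could not place ", J, " sources at the requested separation")
    }
    amp <- stats::runif(J, 0.5, 1)
    img <- matrix(0, N, N)
    peaks <- matrix(0, J, 2)
    for (j in seq_len(J)) {
      r <- sqrt(sum((pos[j, ] - ctr)^2))
      th <- atan2(pos[j, 1] - ctr, pos[j, 2] - ctr)
      p <- render_psf(coeffs, r, th, grid)
      img <- img + amp[j] * p
      pk <- arrayInd(which.max(p), dim(p))
      peaks[j, ] <- pk
    }
    truth <- data.frame(row = pos[, 1], col = pos[, 2],
                        radius = sqrt((pos[, 1] - ctr)^2 + (pos[, 2] - ctr)^2),
                        theta = atan2(pos[, 1] - ctr, pos[, 2] - ctr),
                        amplitude = amp,
                        peak_row = peaks[, 1], peak_col = peaks[, 2])
    noisy <- add_noise(img, noise)
    list(cal = calibration_image(noisy, truth[, c("row", "col")]),
         truth = truth, image_clean = img)
  })
}

#' Blurred image dataset
#'
#' Pairs each source image with a sampled coefficient set and blurs it
#' with the requested forward model (`"ring"` for the fast exact LRI
#' model, `"true"` for the brute-force superposition oracle), optionally
#' adding noise.  A manifest of seeds and coefficients makes the dataset
#' bit-reproducible.
#'
#' @param source_images list of square matrices (or a single matrix).
#' @param grid an [optical_grid] matching the images.
#' @param coeff_sets list of [seidel_coefficients], one per image
#'   (recycled); default sampled uniformly in 0-3 waves.
#' @param forward `"ring"` or `"true"`.
#' @param noise a [noise_spec].
#' @param seed integer seed (controls default coefficient sampling).
#' @return list of records `list(blurred, truth, coeffs)` with a
#'   `manifest` attribute.
#' @export
make_blurred_dataset <- function(source_images, grid, coeff_sets = NULL,
                                 forward = c("ring", "true"),
                                 noise = noise_spec("none"), seed = 1L) {
  forward <- match.arg(forward)
  if (is.matrix(source_images)) source_images <- list(source_images)
  n <- length(source_images)
  coeff_sets <- coeff_sets %||% sample_seidel_coefficients(n, seed = seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    g <- source_images[[i]]
    co <- coeff_sets[[(i - 1) %% length(coeff_sets) + 1]]
    f <- if (forward == "ring") {
      ring_convolve(g, render_radial_psf_stack(co, grid))
    } else {
      true_blur(g, co, grid)
    }
    out[[i]] <- list(blurred = add_noise(f, noise), truth = g, coeffs = co)
  }
  attr(out, "manifest") <- list(seed = seed, forward = forward,
                                noise = unclass(noise),
                                coeffs = lapply(coeff_sets, unclass))
  out
}

#' Synthetic light-sheet bead volume
#'
#' Scatters point emitters in a volume at a minimum separation and
#' renders each with the light-sheet PSF for its position along the
#' sheet-focus axis, then applies noise.  Ground-truth voxel positions
#' are returned for resolution measurements.
#'
#' @param model an [lsfm_psf_model].
#' @param n_beads number of beads.
#' @param dims volume dimensions `c(Nu, Nv, Nt)` (sheet-focus axis
#'   first).
#' @param noise a [noise_spec].
#' @param min_separation minimum pairwise distance (voxels).
#' @param seed integer seed.
#' @param margin keep-out border (voxels) on every axis.
#' @return list with `volume` and `beads` (data.frame `u`, `v`, `t`,
#'   `amplitude`).
#' @export
make_bead_volume <- function(model, n_beads, dims,
                             noise = noise_spec("none"),
                             min_separation = 8, seed = 1L, margin = 5) {
  stopifnot(n_beads >= 1, length(dims) == 3)
  if (any(dims - 2 * margin + 1 < 1))
    stop("margin too large for the requested volume dimensions")
  with_seed(seed, {
    pos <- matrix(0, 0, 3)
    tries <- 0
    while (nrow(pos) < n_beads) {
      cand <- round(c(stats::runif(1, margin, dims[1] - margin + 1),
                      stats::runif(1, margin, dims[2] - margin + 1),
                      stats::runif(1, margin, dims[3] - margin + 1)))
      if (nrow(pos) == 0 ||
          all(sqrt(colSums((t(pos) - cand)^2)) >= min_separation))
        pos <- rbind(pos, cand)
      tries <- tries + 1
      if (tries > 1e4)
        stop("could not place ", n_beads, " beads at the requested separation")
    }
    amp <- stats::runif(n_beads, 0.5, 1)
    vol <- array(0, dims)
    u0 <- (dims[1] + 1) / 2
    for (b in seq_len(n_beads)) {
      psf <- lsfm_psf(model, pos[b, 1] - u0)
      vol <- add_psf_at(vol, psf, pos[b, ], amp[b])
    }
    beads <- data.frame(u = pos[, 1], v = pos[, 2], t = pos[, 3],
                        amplitude = amp)
    list(volume = add_noise(vol, noise), beads = beads)
  })
}

# add `amp * psf` (odd-dimensioned 3D array) into `vol` centered at
# integer voxel `at`, clipping at the volume boundary
add_psf_at <- function(vol, psf, at, amp = 1) {
  dp <- dim(psf); dv <- dim(vol)
  h <- (dp - 1) %/% 2
  for (ax in 1:3) stopifnot(dp[ax] %% 2 == 1)
  lo <- pmax(at - h, 1); hi <- pmin(at + h, dv)
  plo <- lo - (at - h) + 1; phi <- dp - ((at + h) - hi)
  vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
    vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] +
    amp * psf[plo[1]:phi[1], plo[2]:phi[2], plo[3]:phi[3]]
  vol
}

#' Measured signal-to-noise ratio
#'
#' `10*log10(mean(signal^2) / var(noisy - signal))`, the definition used
#' by [noise_spec].
#'
#' @param noisy,signal arrays of identical shape.
#' @return SNR in dB.
#' @export
measure_snr <- function(noisy, signal) {
  10 * log10(mean(signal^2) / stats::var(as.vector(noisy - signal)))
}
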