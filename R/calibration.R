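# Single-image Seidel calibration: detect scattered point sources,
# estimate the optical center, and fit the five primary aberration
# coefficients by matching rendered PSFs to the measured ones at their
# field positions.

#' Detect point sources in a calibration image
#'
#' Local-maximum detection above a robust background threshold, with
#' sub-pixel refinement by intensity centroid and a minimum-separation
#' constraint (the brighter of two close detections is kept).
#'
#' @param image nonnegative matrix.
#' @param threshold_sigmas detection threshold in robust standard
#'   deviations (MAD) above the median background.
#' @param min_separation minimum distance between kept detections
#'   (pixels).
#' @param window odd width of the centroid-refinement window.
#' @param min_contrast detection floor as a fraction of the image's
#'   dynamic range, guarding against a near-zero background MAD on
#'   clean synthetic images.
#' @param center optical center used to order detections by radius;
#'   default geometric center.
#' @return data.frame with columns `row`, `col` (sub-pixel, 1-based),
#'   `amplitude` (peak value), `radius`, `theta`, sorted by radius.
#'   Empty when nothing is found.
#' @export
detect_point_sources <- function(image, threshold_sigmas = 5,
                                 min_separation = 10, window = 9,
                                 min_contrast = 0.02, center = NULL) {
  if (any(image < 0)) stop("image must be nonnegative")
  N <- nrow(image); Nc <- ncol(image)
  center <- center %||% c((N + 1) / 2, (Nc + 1) / 2)
  bg <- stats::median(image)
  sig <- stats::mad(image)
  thr <- bg + max(threshold_sigmas * sig, min_contrast * (max(image) - bg),
                  1e-12)
  # 3x3 local maxima, excluding a 1-px border
  cand <- which(image > thr)
  cand <- cand[vapply(cand, function(k) {
    i <- (k - 1) %% N + 1; j <- (k - 1) %/% N + 1
    if (i <= 1 || i >= N || j <= 1 || j >= Nc) return(FALSE)
    all(image[i, j] >= image[(i - 1):(i + 1), (j - 1):(j + 1)])
  }, logical(1))]
  if (!length(cand))
    return(data.frame(row = numeric(0), col = numeric(0),
                      amplitude = numeric(0), radius = numeric(0),
                      theta = numeric(0)))
  ord <- order(image[cand], decreasing = TRUE)
  cand <- cand[ord]
  pr <- (cand - 1) %% N + 1
  pc <- (cand - 1) %/% N + 1
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    if (!any(keep)) { keep[k] <- TRUE; next }
    d <- sqrt((pr[k] - pr[keep])^2 + (pc[k] - pc[keep])^2)
    if (all(d >= min_separation)) keep[k] <- TRUE
    else warning("dropping detection closer than min_separation to a brighter one")
  }
  pr <- pr[keep]; pc <- pc[keep]
  h <- (window - 1) %/% 2
  ref <- t(vapply(seq_along(pr), function(k) {
    ri <- max(1, pr[k] - h):min(N, pr[k] + h)
    ci <- max(1, pc[k] - h):min(Nc, pc[k] + h)
    w <- pmax(image[ri, ci] - bg, 0)
    s <- sum(w)
    if (s <= 0) return(c(pr[k], pc[k]))
    c(sum(ri * rowSums(w)) / s, sum(ci * colSums(w)) / s)
  }, numeric(2)))
  out <- data.frame(row = ref[, 1], col = ref[, 2],
                    amplitude = image[cbind(pr, pc)])
  out$radius <- sqrt((out$row - center[1])^2 + (out$col - center[2])^2)
  out$theta <- atan2(out$row - center[1], out$col - center[2])
  out[order(out$radius), , drop = FALSE]
}

#' Estimate the optical center of a rotationally symmetric image
#'
#' Finds the center maximizing the correlation between the image and its
#' 180-degree-rotated copy (computed for all candidate centers at once
#' through the FFT autoconvolution), with quadratic sub-pixel
#' refinement.  Falls back to the geometric center when the correlation
#' landscape is flat.
#'
#' @param image matrix with nonzero content.
#' @param max_shift largest allowed offset from the geometric center
#'   (pixels).
#' @return numeric `(row, col)` center, possibly half-integer.
#' @export
estimate_optical_center <- function(image, max_shift = nrow(image) / 4) {
  if (stats::sd(image) < 1e-12)
    stop("cannot estimate a center from a constant image")
  N <- nrow(image); Nc <- ncol(image)
  x <- image - mean(image)
  # conv[k] = sum_x img(x) img(k - x); its argmax k corresponds to center
  # k/2, determined modulo half the image period
  conv <- Re(ifft2(fft2(x)^2))
  geo <- c((N + 1) / 2, (Nc + 1) / 2)
  ks <- expand.grid(kr = 0:(N - 1), kc = 0:(Nc - 1))
  # each lag k admits centers (k + 2)/2 + m*N/2; pick the branch nearest
  # the geometric center
  unwrap <- function(c0, g, n) {
    cand <- c0 + (-2:2) * (n / 2)
    cand[which.min(abs(cand - g))]
  }
  cr <- vapply((ks$kr + 2) / 2, unwrap, numeric(1), g = geo[1], n = N)
  cc <- vapply((ks$kc + 2) / 2, unwrap, numeric(1), g = geo[2], n = Nc)
  ok <- abs(cr - geo[1]) <= max_shift & abs(cc - geo[2]) <= max_shift
  v <- as.vector(conv)[ok]
  if (diff(range(v)) < 1e-9 * max(abs(v), 1e-300)) return(geo)
  best <- which.max(v)
  c(cr[ok][best], cc[ok][best])
}

#' Calibration image container
#'
#' Bundles a calibration image of scattered point sources with the
#' source table used by [fit_seidel].  Source positions should be the
#' *nominal* (unaberrated) image positions when known (e.g. from the
#' synthetic generator); detected positions are an acceptable substitute
#' but make the distortion coefficient nearly unidentifiable, since its
#' only effect is a field-dependent displacement.
#'
#' @param image nonnegative matrix.
#' @param sources data.frame with columns `row`, `col` (1-based,
#'   sub-pixel allowed); other columns are preserved.
#' @param center optical center `(row, col)`; default geometric.
#' @return object of class `calibration_image`.
#' @export
calibration_image <- function(image, sources, center = NULL) {
  N <- nrow(image)
  center <- center %||% c((N + 1) / 2, (ncol(image) + 1) / 2)
  stopifnot(is.data.frame(sources), all(c("row", "col") %in% names(sources)))
  sources$radius <- sqrt((sources$row - center[1])^2 +
                         (sources$col - center[2])^2)
  sources$theta <- atan2(sources$row - center[1], sources$col - center[2])
  structure(list(image = image, sources = sources, center = center),
            class = "calibration_image")
}

#' @export
print.calibration_image <- function(x, ...) {
  cat(sprintf("Calibration image %dx%d with %d sources, center (%.1f, %.1f)\n",
              nrow(x$image), ncol(x$image), nrow(x$sources),
              x$center[1], x$center[2]))
  invisible(x)
}

# Render the full-field PSF of one source and (optionally) its five
# coefficient gradients, on the padded pupil grid of the given optical
# grid, cropped to the N x N image.  Intensity scale is the raw squared
# modulus (amplitude nuisance parameters absorb it).
psf_field_model <- function(coeffs, r, theta, grid, gradients = TRUE,
                            freeze = NULL) {
  N <- grid$N
  L <- grid$pupil_samples
  b <- pupil_basis(L, grid$pupil_fill)
  H <- min(r / grid$r_max, 1)
  w <- unclass(as_seidel(coeffs))
  cpsi <- cos(theta) * b$X + sin(theta) * b$Y
  basis <- list(sphere = b$rho4,
                coma = H * b$rho2 * cpsi,
                astigmatism = H^2 * cpsi^2,
                field_curvature = H^2 * b$rho2,
                distortion = H^3 * cpsi)
  W <- basis[[1]] * w[1] + basis[[2]] * w[2] + basis[[3]] * w[3] +
       basis[[4]] * w[4] + basis[[5]] * w[5]
  off <- floor((L - N) / 2)
  cpad <- floor(L / 2) + 1
  shift <- c(off + (N + 1) / 2 + r * sin(theta) - cpad,
             off + (N + 1) / 2 + r * cos(theta) - cpad)
  ramp <- (shift[1] * b$my + shift[2] * b$mx) / L
  P <- matrix(0 + 0i, L, L)
  P[b$idx] <- exp(2i * pi * (W + ramp))
  A <- fft2(P)
  crop_of <- function(m) fftshift2(m)[off + seq_len(N), off + seq_len(N)]
  out <- list(psf = crop_of(Re(A)^2 + Im(A)^2))
  if (gradients) {
    out$grad <- lapply(seq_along(basis), function(k) {
      if (!is.null(freeze) && freeze[k]) return(matrix(0, N, N))
      Pk <- matrix(0 + 0i, L, L)
      Pk[b$idx] <- 2i * pi * basis[[k]] * P[b$idx]
      Ak <- fft2(Pk)
      crop_of(2 * (Re(A) * Re(Ak) + Im(A) * Im(Ak)))
    })
  }
  out
}

#' Fit Seidel coefficients to a calibration image
#'
#' Estimates the five primary Seidel coefficients from a single image of
#' scattered point sources.  The whole image is modelled jointly as the
#' sum of the PSFs rendered at every source's field position plus a
#' constant background; per-source amplitudes and the background are
#' nuisance parameters solved in closed form (linear least squares)
#' every iteration, and the coefficient gradient is computed
#' analytically through the pupil function and followed with
#' adaptive-moment steps.  The joint model handles overlapping PSFs,
#' which are unavoidable at multi-wave aberrations.  The problem is
#' nonconvex, so optional random restarts are kept (best final loss
#' wins).
#'
#' @param cal a [calibration_image].  Source positions should be the
#'   nominal (unaberrated) positions when known; see
#'   [calibration_image] for the distortion caveat with detected
#'   positions.
#' @param grid the [optical_grid] of the imaging system.
#' @param cfg a [solver_config]; `max_iters` and `step_size` control the
#'   coefficient optimizer (defaults here: 150 iterations, step 0.05
#'   waves).
#' @param window odd width of the per-source diagnostic window used for
#'   `per_source_residuals`.
#' @param freeze_distortion fix the distortion coefficient at 0 (useful
#'   when source positions come from peak detection, which cannot
#'   constrain distortion).
#' @param n_starts number of optimizer starts beyond the first (extra
#'   starts are seeded random); a start that already fits to numerical
#'   precision skips the rest.
#' @param init `"grid"` (default) probes a coarse 3-level lattice over
#'   the coefficient box with amplitudes solved in closed form and
#'   starts the optimizer from the best cell, a cheap globalization that
#'   rescues most local-minimum failures of the nonconvex fit;
#'   `"zeros"` starts from the all-zero vector.
#' @param bounds box constraint on each coefficient, in waves.
#' @return a `seidel_fit_result`: list with `coefficients`
#'   ([seidel_coefficients]), `amplitudes`, `per_source_residuals`
#'   (relative L2 in the diagnostic window), `loss_trace` (best start)
#'   and `n_sources_used`.
#' @export
fit_seidel <- function(cal, grid, cfg = solver_config(max_iters = 150,
                                                      step_size = 0.05),
                       window = 31, freeze_distortion = FALSE,
                       n_starts = 1, init = c("grid", "zeros"),
                       bounds = c(0, 4)) {
  init <- match.arg(init)
  stopifnot(inherits(cal, "calibration_image"), inherits(grid, "optical_grid"))
  src <- cal$sources
  if (!nrow(src)) stop("no detected sources in calibration image")
  if (all(src$radius < 1e-6))
    warning("only on-axis sources present; off-axis coefficients are unconstrained")
  N <- nrow(cal$image)
  stopifnot(N == grid$N)
  J <- nrow(src)
  y <- as.vector(cal$image)
  freeze <- c(FALSE, FALSE, FALSE, FALSE, isTRUE(freeze_distortion))

  eval_fit <- function(wvec, gradients = TRUE) {
    mods <- lapply(seq_len(J), function(j)
      psf_field_model(wvec, src$radius[j], src$theta[j], grid,
                      gradients, freeze))
    X <- cbind(vapply(mods, function(m) as.vector(m$psf), numeric(N * N)), 1)
    cf <- tryCatch(qr.coef(qr(X), y), error = function(e) rep(0, J + 1))
    cf[!is.finite(cf)] <- 0
    r <- as.vector(X %*% cf) - y
    loss <- sum(r^2)
    grad <- numeric(5)
    if (gradients) {
      rm_ <- matrix(r, N, N)
      for (k in 1:5)
        grad[k] <- sum(vapply(seq_len(J), function(j)
          2 * cf[j] * sum(rm_ * mods[[j]]$grad[[k]]), numeric(1)))
    }
    list(loss = loss, grad = grad, amps = cf[seq_len(J)],
         background = cf[J + 1], resid = matrix(r, N, N))
  }

  start1 <- rep(0, 5)
  if (init == "grid") {
    lv <- seq(bounds[1], min(bounds[2], 3), length.out = 7)[c(2, 4, 6)]
    cand <- as.matrix(expand.grid(lv, lv, lv, lv,
                                  if (freeze[5]) 0 else lv))
    gl <- apply(cand, 1, function(wv) eval_fit(wv, gradients = FALSE)$loss)
    start1 <- as.numeric(cand[which.min(gl), ])
  }
  starts <- list(start1)
  if (init == "grid" && any(start1 != 0))
    starts <- c(starts, list(rep(0, 5)))   # aberration-free start, cheap
  if (n_starts > 1) {
    extra <- with_seed(cfg$seed, lapply(seq_len(n_starts - 1),
                                        function(i) stats::runif(5, 0, 2)))
    starts <- c(starts, extra)
  }
  best <- NULL
  data_norm <- sum(y^2)
  for (s in seq_along(starts)) {
    wv <- starts[[s]]
    if (freeze[5]) wv[5] <- 0
    m1 <- v1 <- numeric(5)
    b1 <- 0.9; b2 <- 0.999
    trace <- numeric(cfg$max_iters)
    for (it in seq_len(cfg$max_iters)) {
      ev <- eval_fit(wv)
      if (!is.finite(ev$loss)) stop("non-finite loss in Seidel fit")
      trace[it] <- ev$loss
      m1 <- b1 * m1 + (1 - b1) * ev$grad
      v1 <- b2 * v1 + (1 - b2) * ev$grad^2
      wv <- wv - cfg$step_size * (m1 / (1 - b1^it)) /
            (sqrt(v1 / (1 - b2^it)) + 1e-12)
      wv <- pmin(pmax(wv, bounds[1]), bounds[2])
      if (freeze[5]) wv[5] <- 0
      if (it > 20 && abs(trace[it - 1] - trace[it]) <=
            cfg$tol * max(trace[it - 1], 1e-300)) {
        trace <- trace[seq_len(it)]
        break
      }
    }
    fin <- eval_fit(wv, gradients = FALSE)
    if (is.null(best) || fin$loss < best$loss)
      best <- list(w = wv, loss = fin$loss, trace = trace,
                   amps = fin$amps, resid = fin$resid)
    if (best$loss <= 1e-8 * data_norm) break   # essentially exact fit
  }
  # per-source residual diagnostic in a window around each source
  half <- (window - 1) %/% 2
  psr <- vapply(seq_len(J), function(j) {
    cr <- round(src$row[j]); cc <- round(src$col[j])
    ri <- max(1, cr - half):min(N, cr + half)
    ci <- max(1, cc - half):min(N, cc + half)
    sqrt(sum(best$resid[ri, ci]^2)) /
      max(sqrt(sum(cal$image[ri, ci]^2)), 1e-300)
  }, numeric(1))
  structure(list(coefficients = as_seidel(best$w),
                 amplitudes = best$amps,
                 per_source_residuals = psr,
                 loss_trace = best$trace,
                 n_sources_used = J),
            class = "seidel_fit_result")
}

#' @export
print.seidel_fit_result <- function(x, ...) {
  cat("Seidel fit over", x$n_sources_used, "sources\n")
  print(x$coefficients)
  cat(sprintf("median per-source residual: %.3g\n",
              stats::median(x$per_source_residuals)))
  invisible(x)
}
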