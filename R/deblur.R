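# Inverse solvers: TV-regularized iterative least squares with the ring
# (or LSI) forward model, classical Wiener / Richardson-Lucy baselines,
# and blind spherical-aberration estimation by sharpness maximization.

#' Solver configuration
#'
#' Settings for the iterative least-squares solvers used by
#' [ring_deconvolve], [standard_deconvolve] (iterative mode) and
#' [sheet_deconvolve]: conjugate gradients for the pure quadratic case
#' (`tv_weight = 0`, `nonneg = FALSE`) and accelerated projected
#' gradient descent otherwise.
#'
#' @param max_iters maximum iterations (>= 1).
#' @param step_size relative step multiplier for the projected-gradient
#'   path (the absolute step is set automatically from the operator
#'   norm); images are assumed normalized to about `[0, 1]`.
#' @param tv_weight weight of the anisotropic total-variation penalty
#'   (L1 norm of forward differences); `0` disables it.
#' @param nonneg project the estimate onto the nonnegative orthant each
#'   step (default `TRUE`, appropriate for fluorescence data).
#' @param tol stop when the relative loss change falls below this.
#' @param seed integer seed for any randomized choices (e.g. random
#'   initialization).
#' @return an object of class `solver_config`.
#' @export
solver_config <- function(max_iters = 300, step_size = 0.1, tv_weight = 1e-4,
                          nonneg = TRUE, tol = 1e-6, seed = 1L) {
  stopifnot(max_iters >= 1, tol > 0, tv_weight >= 0)
  structure(list(max_iters = as.integer(max_iters), step_size = step_size,
                 tv_weight = tv_weight, nonneg = isTRUE(nonneg), tol = tol,
                 seed = as.integer(seed)),
            class = "solver_config")
}

deblur_result <- function(estimate, loss_trace, iterations) {
  structure(list(estimate = estimate, loss_trace = loss_trace,
                 iterations_run = iterations),
            class = "deblur_result")
}

#' @export
print.deblur_result <- function(x, ...) {
  cat(sprintf("Deblur result: %d iterations, final loss %.6g\n",
              x$iterations_run,
              if (length(x$loss_trace)) utils::tail(x$loss_trace, 1) else NA))
  invisible(x)
}

# Anisotropic TV value and subgradient (L1 of forward differences with
# zero boundary flux), for arrays of any dimensionality.
tv_penalty <- function(x) {
  val <- 0
  grad <- array(0, dim(x) %||% length(x))
  d <- dim(x) %||% length(x)
  nd <- length(d)
  for (ax in seq_len(nd)) {
    n <- d[ax]
    if (n < 2) next
    idx1 <- lapply(d, seq_len); idx0 <- idx1
    idx1[[ax]] <- 2:n; idx0[[ax]] <- 1:(n - 1)
    diffx <- do.call(`[`, c(list(x), idx1, drop = FALSE)) -
             do.call(`[`, c(list(x), idx0, drop = FALSE))
    val <- val + sum(abs(diffx))
    s <- sign(diffx)
    g1 <- array(0, d); g0 <- array(0, d)
    g1 <- do.call(`[<-`, c(list(g1), idx1, list(s)))
    g0 <- do.call(`[<-`, c(list(g0), idx0, list(s)))
    grad <- grad + (g1 - g0)
  }
  list(value = val, grad = grad)
}

# Conjugate gradients on the normal equations A^T A x = A^T f: the exact
# solver for the pure least-squares case (no TV, no projection), where
# the objective is a convex quadratic.
cg_least_squares <- function(f, forward, adjoint, x0, cfg) {
  x <- x0
  atf <- adjoint(f)
  ata <- function(z) adjoint(forward(z))
  r <- atf - ata(x)
  p <- r
  rs <- sum(r^2)
  trace <- numeric(0)
  it <- 0
  for (it in seq_len(cfg$max_iters)) {
    ap <- ata(p)
    denom <- sum(p * ap)
    if (denom <= 0) break
    alpha <- rs / denom
    x <- x + alpha * p
    r <- r - alpha * ap
    rs_new <- sum(r^2)
    loss <- sum((forward(x) - f)^2)
    if (!is.finite(loss))
      stop("solver diverged: non-finite loss at iteration ", it)
    trace <- c(trace, loss)
    if (sqrt(rs_new) <= cfg$tol * max(sqrt(sum(atf^2)), 1e-300)) break
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  deblur_result(x, trace, it)
}

# Accelerated (Nesterov) projected gradient descent on
# ||A x - f||^2 + tv * TV(x), with projection onto x >= 0 when
# requested.  The step is set automatically to 1/L with L the largest
# eigenvalue of 2 A^T A found by power iteration, scaled by
# `step_size / 0.1` so the configured step acts as a relative
# multiplier.  The best iterate seen is returned (acceleration is not
# monotone).  Pure least squares (tv_weight 0, nonneg off) dispatches to
# conjugate gradients, the exact solver for that convex quadratic.
adam_least_squares <- function(f, forward, adjoint, x0, cfg) {
  if (cfg$tv_weight == 0 && !cfg$nonneg)
    return(cg_least_squares(f, forward, adjoint, x0, cfg))
  dims <- dim(x0) %||% length(x0)
  z <- with_seed(cfg$seed, array(stats::rnorm(length(x0)), dims))
  nz <- 1
  for (i in 1:12) {
    z <- adjoint(forward(z))
    nz <- sqrt(sum(z^2))
    if (nz == 0) break
    z <- z / nz
  }
  L <- max(2 * nz, 1e-12)
  step <- (cfg$step_size / 0.1) / L
  x <- x0
  xp <- x0
  tk <- 1
  trace <- numeric(0)
  prev <- Inf
  best_loss <- Inf
  best_x <- x0
  it <- 0
  for (it in seq_len(cfg$max_iters)) {
    tk1 <- (1 + sqrt(1 + 4 * tk^2)) / 2
    y <- x + ((tk - 1) / tk1) * (x - xp)
    r <- forward(y) - f
    grad <- 2 * adjoint(r)
    loss <- sum((forward(x) - f)^2)
    if (cfg$tv_weight > 0) {
      tv <- tv_penalty(y)
      grad <- grad + cfg$tv_weight * tv$grad
      loss <- loss + cfg$tv_weight * tv_penalty(x)$value
    }
    if (!is.finite(loss))
      stop("solver diverged: non-finite loss at iteration ", it)
    trace <- c(trace, loss)
    if (loss < best_loss) { best_loss <- loss; best_x <- x }
    xp <- x
    x <- y - step * grad
    if (cfg$nonneg) x[x < 0] <- 0
    tk <- tk1
    if (it > 10 && abs(prev - loss) <= cfg$tol * max(prev, .Machine$double.eps))
      break
    prev <- loss
  }
  deblur_result(best_x, trace, it)
}

#' Ring deconvolution
#'
#' Recovers the object from an image blurred by a radially varying PSF by
#' solving the TV-regularized least-squares problem
#' \deqn{\hat g = \arg\min_{\bar g} \|f - \bar g \circledcirc h\|_2^2
#'   + \lambda\,TV(\bar g)}
#' by accelerated projected gradient descent (conjugate gradients in the
#' unregularized case), using ring convolution as the forward model and
#' its exact adjoint for the data-fidelity gradient.
#'
#' @param f blurred square image (ideally normalized to `[0, 1]`).
#' @param h a [radial_psf_stack] or prebuilt [ring_operator].
#' @param cfg a [solver_config].
#' @param spec optional [polar_grid_spec] forwarded to [ring_operator].
#' @param init optional initial estimate; defaults to `f` itself.
#' @return a `deblur_result` with the estimate, per-iteration loss trace
#'   and iteration count.
#' @export
ring_deconvolve <- function(f, h, cfg = solver_config(), spec = NULL,
                            init = NULL) {
  op <- if (inherits(h, "ring_operator")) h else ring_operator(h, spec)
  check_image_stack(f, op)
  x0 <- init %||% f
  adam_least_squares(f, op$forward, op$adjoint, x0, cfg)
}

#' Standard (space-invariant) deconvolution baselines
#'
#' Deconvolution with a single PSF under the LSI assumption:
#' `"wiener"` is the closed-form frequency-domain filter with
#' noise-to-signal parameter `nsr`; `"richardson_lucy"` is the classical
#' multiplicative EM scheme (nonnegativity- and flux-preserving);
#' `"iterative_ls"` solves the same TV-regularized least squares as
#' [ring_deconvolve] but with standard convolution as the forward model.
#'
#' @param f blurred square image.
#' @param psf single PSF, same size as `f`, centered at the optical
#'   center, unit sum.
#' @param method one of `"wiener"`, `"richardson_lucy"`,
#'   `"iterative_ls"`.
#' @param cfg a [solver_config] (iteration count used by RL and LS).
#' @param nsr Wiener noise-to-signal power ratio.
#' @return a `deblur_result`.
#' @export
standard_deconvolve <- function(f, psf,
                                method = c("wiener", "richardson_lucy",
                                           "iterative_ls"),
                                cfg = solver_config(), nsr = 1e-3) {
  method <- match.arg(method)
  stopifnot(all(dim(f) == dim(psf)))
  if (sum(abs(psf)) == 0) stop("PSF is identically zero")
  n <- nrow(f)
  ctr <- c((n + 1) / 2, (n + 1) / 2)
  ky <- freq_index(n) / n
  kx <- freq_index(n) / n
  ramp <- exp(2i * pi * outer(ky * (ctr[1] - 1), kx * (ctr[2] - 1), "+"))
  Hh <- fft2(psf) * ramp
  if (method == "wiener") {
    Gh <- Conj(Hh) * fft2(f) / (Mod(Hh)^2 + nsr)
    est <- Re(ifft2(Gh))
    if (cfg$nonneg) est[est < 0] <- 0
    return(deblur_result(est, numeric(0), 0L))
  }
  fwd <- function(x) Re(ifft2(fft2(x) * Hh))
  adj <- function(x) Re(ifft2(fft2(x) * Conj(Hh)))
  if (method == "richardson_lucy") {
    if (any(f < 0)) stop("Richardson-Lucy requires nonnegative input")
    x <- matrix(mean(f), n, n)
    trace <- numeric(cfg$max_iters)
    for (it in seq_len(cfg$max_iters)) {
      ax <- fwd(x)
      x <- x * adj(f / pmax(ax, 1e-12))
      trace[it] <- sum((ax - f)^2)
    }
    return(deblur_result(x, trace, cfg$max_iters))
  }
  adam_least_squares(f, fwd, adj, f, cfg)
}

#' Blind deconvolution of spherical aberration
#'
#' Estimates the spherical Seidel coefficient of a (near) space-invariant
#' system from a single blurry image, with no calibration data.  At each
#' step a center PSF is rendered from the current coefficient, the image
#' is deconvolved with it, and the negative sum of the absolute spatial
#' gradient of the result (a surrogate for sharpness) is used as the
#' loss; the coefficient is updated by an adaptive-moment gradient step
#' on a finite-difference estimate of the loss derivative.
#'
#' @param f blurry nonnegative square image.
#' @param grid an [optical_grid] matching `f`.
#' @param cfg [solver_config] whose `max_iters` bounds the *inner*
#'   deconvolution iterations (default 60 Richardson-Lucy updates).
#' @param inner_method deconvolution used inside the sharpness loss.
#' @param bounds search interval for the coefficient, in waves.
#' @param init initial coefficient (waves); because the sharpness
#'   landscape is flat when the trial PSF is far too small, the search
#'   first probes a coarse grid over `bounds` and starts from the best
#'   of `init` and the grid, then refines with adaptive-moment steps on
#'   a finite-difference derivative.
#' @param outer_iters coefficient refinement steps.
#' @param step_size Adam step for the coefficient, in waves.
#' @return list with `sphere` (estimated coefficient, waves), `result`
#'   (final `deblur_result`) and `loss_trace`.
#' @export
blind_deconvolve_spherical <- function(f, grid,
                                       cfg = solver_config(max_iters = 60,
                                                           tv_weight = 0),
                                       inner_method = "richardson_lucy",
                                       bounds = c(0, 3), init = 0.5,
                                       outer_iters = 25, step_size = 0.05) {
  stopifnot(inherits(grid, "optical_grid"), nrow(f) == grid$N)
  if (any(!is.finite(f))) stop("input image must be finite")
  if (inner_method == "richardson_lucy") f <- pmax(f, 0)
  sharp_loss <- function(w) {
    psf <- render_psf(seidel_coefficients(sphere = w), 0, 0, grid,
                      normalize = "sum")
    est <- standard_deconvolve(f, psf, inner_method, cfg)$estimate
    dx <- est[, -1] - est[, -ncol(est)]
    dy <- est[-1, ] - est[-nrow(est), ]
    -(sum(abs(dx)) + sum(abs(dy)))
  }
  # coarse probe: the landscape is plateaued below the true coefficient,
  # so a local search from an arbitrary start can stall
  wgrid <- unique(c(init, seq(bounds[1], bounds[2], by = 0.25)))
  lgrid <- vapply(wgrid, sharp_loss, numeric(1))
  if (any(!is.finite(lgrid))) stop("non-finite sharpness loss in blind search")
  w <- wgrid[which.min(lgrid)]
  m <- v <- 0
  b1 <- 0.9; b2 <- 0.999
  delta <- 0.05
  trace <- numeric(outer_iters)
  clamped <- FALSE
  for (it in seq_len(outer_iters)) {
    lo <- sharp_loss(max(w - delta, bounds[1]))
    hi <- sharp_loss(min(w + delta, bounds[2]))
    gr <- (hi - lo) / (min(w + delta, bounds[2]) - max(w - delta, bounds[1]))
    if (!is.finite(gr)) stop("non-finite sharpness loss in blind search")
    trace[it] <- (lo + hi) / 2
    m <- b1 * m + (1 - b1) * gr
    v <- b2 * v + (1 - b2) * gr^2
    w_new <- w - step_size * (m / (1 - b1^it)) / (sqrt(v / (1 - b2^it)) + 1e-8)
    if (w_new < bounds[1] || w_new > bounds[2]) clamped <- TRUE
    w <- min(max(w_new, bounds[1]), bounds[2])
  }
  if (clamped)
    warning("spherical coefficient hit the search bounds during blind fit")
  psf <- render_psf(seidel_coefficients(sphere = w), 0, 0, grid,
                    normalize = "sum")
  res <- standard_deconvolve(f, psf, inner_method, cfg)
  list(sphere = w, result = res, loss_trace = trace)
}
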