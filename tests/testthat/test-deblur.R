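# Inverse solvers: ring deconvolution, standard baselines, blind search.

test_that("identity optics deconvolve to the observed image", {
  N <- 33
  spec <- polar_grid_spec(N, num_radii = 17, max_radius = 16)
  psfs <- lapply(0:16, function(r) { m <- matrix(0, N, N); m[17, 17 + r] <- 1; m })
  st <- radial_psf_stack(psfs, 0:16)
  op <- ring_operator(st, spec, flat_field = TRUE)
  f <- smooth_blobs(N, seed = 2, sigma = 2, margin = 10)
  res <- ring_deconvolve(f, op, solver_config(max_iters = 60, tv_weight = 0))
  expect_lt(rel_l2(res$estimate, f), 0.03)
})

test_that("noiseless ring deconvolution beats the blurred input by 3 dB", {
  N <- 64
  og <- optical_grid(N)
  st <- render_radial_psf_stack(seidel_coefficients(0, 1, 0.5, 0.5, 0), og)
  op <- ring_operator(st)
  g <- make_test_image(N, seed = 3)
  f <- op$forward(g)
  res <- ring_deconvolve(f, op, solver_config(max_iters = 150))
  expect_gt(psnr_of(res$estimate, g), psnr_of(f, g) + 3)
  expect_true(all(is.finite(res$loss_trace)))
  # loss settles under the decayed steps: the last 10% of iterations
  # stay within a sliver of the best loss
  tail_tr <- utils::tail(res$loss_trace, ceiling(0.1 * length(res$loss_trace)))
  expect_lt(max(tail_tr) / min(res$loss_trace) - 1, 0.01)
})

test_that("ring deconvolution outperforms the center-PSF baseline off-axis", {
  N <- 64
  og <- optical_grid(N)
  co <- seidel_coefficients(0, 1, 0.5, 0.5, 0)
  st <- render_radial_psf_stack(co, og)
  op <- ring_operator(st)
  g <- make_test_image(N, seed = 11)
  f <- op$forward(g)
  ring <- ring_deconvolve(f, op, solver_config(max_iters = 150))$estimate
  psf_c <- render_psf(co, 0, 0, og, normalize = "sum")
  std <- standard_deconvolve(f, psf_c, "iterative_ls",
                             solver_config(max_iters = 150))$estimate
  ctr <- (N + 1) / 2
  rr <- sqrt((row(g) - ctr)^2 + (col(g) - ctr)^2)
  outer_ann <- rr >= 0.75 * max(rr)
  pa <- function(x, m) 10 * log10(max(g)^2 / mean((x[m] - g[m])^2))
  expect_gt(pa(ring, outer_ann), pa(std, outer_ann))
})

test_that("solver configuration is validated", {
  expect_error(solver_config(max_iters = 0))
  expect_error(solver_config(tol = 0))
  expect_error(solver_config(tv_weight = -1))
})

test_that("delta PSF leaves the image unchanged for every baseline", {
  N <- 32
  f <- smooth_blobs(N, seed = 1)
  d <- matrix(0, N, N); d[(N + 1) / 2 + 0.5, (N + 1) / 2 + 0.5] <- NA
  # exact delta at the (fractional) optical center is not representable;
  # use an odd-sized image instead
  N <- 33
  f <- smooth_blobs(N, seed = 1)
  d <- matrix(0, N, N); d[17, 17] <- 1
  for (m in c("wiener", "richardson_lucy", "iterative_ls")) {
    est <- standard_deconvolve(f, d, m,
                               solver_config(max_iters = 50, tv_weight = 0),
                               nsr = 1e-12)$estimate
    expect_lt(rel_l2(est, f), 0.01)
  }
  expect_error(standard_deconvolve(f, matrix(0, N, N), "wiener"))
})

test_that("Wiener filtering inverts noiseless band-limited blur", {
  N <- 64
  g <- smooth_blobs(N, seed = 6, margin = 12)
  k <- outer(-6:6, -6:6, function(a, b) exp(-(a^2 + b^2) / 6))
  psf <- matrix(0, N, N)
  psf[33 + (-6:6), 33 + (-6:6)] <- k / sum(k)
  f <- conv2o(g, psf)
  est <- standard_deconvolve(f, psf, "wiener", nsr = 1e-10)$estimate
  expect_lt(rel_l2(est, g), 1e-3)
})

test_that("Richardson-Lucy conserves flux at every iteration", {
  N <- 33
  g <- smooth_blobs(N, seed = 4, margin = 8)
  k <- outer(-4:4, -4:4, function(a, b) exp(-(a^2 + b^2) / 4))
  psf <- matrix(0, N, N)
  psf[17 + (-4:4), 17 + (-4:4)] <- k / sum(k)
  f <- conv2o(g, psf)
  x <- matrix(mean(f), N, N)
  for (it in 1:10) {
    prev_flux <- sum(x)
    est <- standard_deconvolve(f, psf, "richardson_lucy",
                               solver_config(max_iters = it))$estimate
    expect_lt(abs(sum(est) / sum(f) - 1), 1e-3)
  }
  expect_error(standard_deconvolve(f - 10, psf, "richardson_lucy"))
})

test_that("iterative least squares matches Wiener on noiseless LSI data", {
  N <- 64
  # band-limit the object relative to the kernel so the comparison is
  # confined to well-conditioned frequencies
  g <- conv2o(smooth_blobs(N, seed = 9, margin = 12), {
    k0 <- outer(-5:5, -5:5, function(a, b) exp(-(a^2 + b^2) / 5))
    p0 <- matrix(0, N, N); p0[33 + (-5:5), 33 + (-5:5)] <- k0 / sum(k0); p0
  })
  k <- outer(-5:5, -5:5, function(a, b) exp(-(a^2 + b^2) / 5))
  psf <- matrix(0, N, N)
  psf[33 + (-5:5), 33 + (-5:5)] <- k / sum(k)
  f <- conv2o(g, psf)
  w <- standard_deconvolve(f, psf, "wiener", nsr = 1e-8)$estimate
  ls <- standard_deconvolve(f, psf, "iterative_ls",
                            solver_config(max_iters = 300, tv_weight = 0,
                                          nonneg = FALSE, tol = 1e-10))$estimate
  expect_lt(rel_l2(ls, w), 0.01)
})

test_that("two random initializations reach the same ring deconvolution loss", {
  N <- 32
  og <- optical_grid(N)
  st <- render_radial_psf_stack(seidel_coefficients(0.3, 0.5, 0.3, 0.3, 0), og)
  op <- ring_operator(st)
  g <- smooth_blobs(N, seed = 12)
  f <- op$forward(g)
  cfg <- solver_config(max_iters = 400, tv_weight = 1e-4, tol = 1e-9)
  set.seed(21); i1 <- matrix(runif(N * N), N)
  set.seed(99); i2 <- matrix(runif(N * N), N)
  l1 <- utils::tail(ring_deconvolve(f, op, cfg, init = i1)$loss_trace, 1)
  l2 <- utils::tail(ring_deconvolve(f, op, cfg, init = i2)$loss_trace, 1)
  expect_lt(abs(l1 - l2) / max(l1, l2), 0.01)
})

test_that("blind spherical search stays finite on degenerate input", {
  N <- 32
  og <- optical_grid(N)
  set.seed(8)
  noise <- matrix(abs(rnorm(N * N)), N)
  out <- suppressWarnings(
    blind_deconvolve_spherical(noise, og,
                               cfg = solver_config(max_iters = 15, tv_weight = 0),
                               outer_iters = 5))
  expect_true(is.finite(out$sphere))
  expect_gte(out$sphere, 0)
  expect_lte(out$sphere, 3)
  expect_true(all(is.finite(out$result$estimate)))
})

test_that("blind search recovers a known spherical coefficient", {
  N <- 64
  og <- optical_grid(N)
  g <- make_test_image(N, seed = 5)
  f <- conv2o(g, render_psf(seidel_coefficients(sphere = 1.5), 0, 0, og,
                            normalize = "sum"))
  out <- blind_deconvolve_spherical(f, og, outer_iters = 15)
  expect_lt(abs(out$sphere - 1.5), 0.3)
  # the deconvolved result is sharper than the input
  gradsum <- function(x) sum(abs(x[, -1] - x[, -ncol(x)])) +
    sum(abs(x[-1, ] - x[-nrow(x), ]))
  expect_gt(gradsum(out$result$estimate), gradsum(f))
})
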