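# Light-sheet forward model, deconvolution and the (alpha, beta) fit.

test_that("the sheet spread profile follows the Gaussian-beam formula", {
  m <- lsfm_psf_model(2, 0.05)
  expect_equal(sigma_profile(m, 0), 2)
  expect_equal(sigma_profile(m, 1 / 0.05), 2 * sqrt(2))
  m0 <- lsfm_psf_model(1.7, 0)
  expect_equal(sigma_profile(m0, c(-30, 0, 42)), rep(1.7, 3))
  expect_error(lsfm_psf_model(-1, 0.1))
  expect_error(lsfm_psf_model(2, -0.1))
})

test_that("sheet PSFs thicken and lose flux away from the waist", {
  m <- lsfm_psf_model(1.5, 0.08)
  us <- c(0, 5, 10, 15)
  zmom <- flux <- numeric(length(us))
  for (i in seq_along(us)) {
    p <- lsfm_psf(m, us[i])
    d3 <- dim(p)[3]
    zprof <- apply(p, 3, sum)
    cz <- sum(seq_len(d3) * zprof) / sum(zprof)
    zmom[i] <- sum((seq_len(d3) - cz)^2 * zprof) / sum(zprof)
    flux[i] <- sum(p)
  }
  expect_true(all(diff(zmom) > 0))
  expect_true(all(diff(flux) < 0))
  # beta = 0: all positions share one PSF
  m0 <- lsfm_psf_model(1.5, 0)
  expect_equal(lsfm_psf(m0, 0), lsfm_psf(m0, 12))
})

test_that("measured PSF sets interpolate convexly and clamp at the ends", {
  m <- lsfm_psf_model(1.5, 0.08)
  us <- c(2, 6, 10)
  set_ <- axial_psf_set(lapply(us, function(u) lsfm_psf(m, u)), us)
  expect_equal(interpolate_psf(6, set_), set_$psfs[[2]])
  mid <- interpolate_psf(8, set_)
  expect_equal(mid, 0.5 * set_$psfs[[2]] + 0.5 * set_$psfs[[3]])
  expect_equal(interpolate_psf(99, set_), set_$psfs[[3]])
  expect_equal(interpolate_psf(-99, set_), set_$psfs[[1]])
})

test_that("sheet convolution matches the brute-force 3D superposition", {
  dims <- c(32, 32, 16)
  m <- lsfm_psf_model(1.2, 0.08, base_psf = make_base_psf_3d(c(7, 7, 11)))
  set.seed(3)
  vol <- array(runif(prod(dims)), dims)
  fs <- sheet_convolve(vol, m)
  fd <- sheet_blur_direct(vol, m)
  expect_lt(rel_l2(fs, fd), 1e-6)
  # impulse: the PSF appears at the impulse's (v, t), on the right slices
  imp <- array(0, dims); imp[16, 20, 8] <- 1
  fi <- sheet_convolve(imp, m)
  p <- ringdeconv:::crop_psf_to(lsfm_psf(m, 16 - 16.5), dims)
  h <- (dim(p) - 1) %/% 2
  expect_lt(rel_l2(fi[(16 - h[1]):(16 + h[1]), (20 - h[2]):(20 + h[2]),
                      (8 - h[3]):(8 + h[3])], p), 1e-10)
})

test_that("a u-invariant sheet PSF reduces to full 3D convolution", {
  dims <- c(32, 32, 16)
  m0 <- lsfm_psf_model(1.2, 0, base_psf = make_base_psf_3d(c(7, 7, 11)))
  set.seed(4)
  vol <- array(0, dims)
  vol[5:28, , ] <- array(runif(24 * 32 * 16), c(24, 32, 16))  # keep u margins
  fs <- sheet_convolve(vol, m0)
  f3 <- conv3o(vol, ringdeconv:::crop_psf_to(lsfm_psf(m0, 0), dims))
  expect_lt(rel_l2(fs[5:28, , ], f3[5:28, , ]), 1e-6)
})

test_that("the sheet operator adjoint passes the inner-product test", {
  dims <- c(24, 24, 12)
  m <- lsfm_psf_model(1.2, 0.1, base_psf = make_base_psf_3d(c(7, 7, 9)))
  op <- ringdeconv:::sheet_operator(m, dims)
  set.seed(6)
  x <- array(rnorm(prod(dims)), dims)
  y <- array(rnorm(prod(dims)), dims)
  ip1 <- sum(op$forward(x) * y)
  ip2 <- sum(x * op$adjoint(y))
  expect_lt(abs(ip1 - ip2) / abs(ip1), 1e-10)
})

test_that("noiseless sheet deconvolution improves synthetic beads by 3 dB", {
  m <- lsfm_psf_model(2, 0.1)
  mb <- make_bead_volume(m, 8, c(48, 32, 24), seed = 4, min_separation = 10,
                         margin = 8)
  f <- mb$volume / max(mb$volume)
  g0 <- array(0, dim(f))
  g0[as.matrix(mb$beads[, 1:3])] <- mb$beads$amplitude / max(mb$volume)
  res <- sheet_deconvolve(f, m, solver_config(max_iters = 200, tv_weight = 0))
  expect_gt(psnr_of(res$estimate, g0), psnr_of(f, g0) + 3)
  # the raw axial width grows away from the waist
  fw_raw <- measure_fwhm(f, mb$beads[, 1:3], axis = 3)
  du <- abs(mb$beads$u - (48 + 1) / 2)
  expect_gt(stats::cor(du, fw_raw, method = "spearman", use = "complete.obs"), 0.5)
})

test_that("sheet deconvolution homogenizes axial resolution beyond the LSI baseline", {
  # noise-limited inversion: with complete noiseless inversion both
  # methods sharpen beads fully and the comparison is degenerate
  m <- lsfm_psf_model(2, 0.1)
  mb <- make_bead_volume(m, 12, c(64, 40, 28), seed = 4, min_separation = 11,
                         margin = 8,
                         noise = noise_spec("gaussian", snr_db = 25, seed = 2))
  f <- mb$volume / max(mb$volume)
  cfg <- solver_config(max_iters = 80, tv_weight = 0, nonneg = FALSE,
                       tol = 1e-10)
  sd_ <- sheet_deconvolve(f, m, cfg)
  ld <- lsi_deconvolve_3d(f, ringdeconv:::crop_psf_to(lsfm_psf(m, 0), dim(f)),
                          cfg)
  fw_sheet <- measure_fwhm(sd_$estimate, mb$beads[, 1:3], axis = 3)
  fw_lsi <- measure_fwhm(ld$estimate, mb$beads[, 1:3], axis = 3)
  expect_lt(mean(fw_sheet, na.rm = TRUE), mean(fw_lsi, na.rm = TRUE))
  expect_lt(stats::sd(fw_sheet, na.rm = TRUE),
            stats::sd(fw_lsi, na.rm = TRUE))
})

test_that("beta = 0 sheet deconvolution agrees with standard 3D deconvolution", {
  m0 <- lsfm_psf_model(1.5, 0, base_psf = make_base_psf_3d(c(7, 7, 9)))
  mb <- make_bead_volume(m0, 6, c(32, 24, 16), seed = 9, min_separation = 8,
                         margin = 6)
  # early-stopped CG: the unregularized minimum-norm solutions of the
  # clipped-u and wrapped-u operators genuinely diverge in their
  # ill-conditioned modes, so the LSI-limit comparison is made in the
  # well-conditioned regime
  cfg <- solver_config(max_iters = 15, tv_weight = 0, nonneg = FALSE,
                       tol = 1e-10)
  a <- sheet_deconvolve(mb$volume, m0, cfg)$estimate
  b <- lsi_deconvolve_3d(mb$volume, ringdeconv:::crop_psf_to(lsfm_psf(m0, 0),
                                                             dim(mb$volume)),
                         cfg)$estimate
  # interior of the u axis (the sheet model clips, the LSI model wraps)
  ii <- 5:28
  expect_lt(rel_l2(a[ii, , ], b[ii, , ]), 0.01)
})

test_that("FWHM measurement matches the Gaussian closed form", {
  dims <- c(21, 21, 21)
  sig <- 2
  vol <- array(0, dims)
  for (i in 1:21) for (j in 1:21) for (k in 1:21)
    vol[i, j, k] <- exp(-((i - 11)^2 + (j - 11)^2 + (k - 11)^2) / (2 * sig^2))
  loc <- matrix(c(11, 11, 11), 1)
  for (ax in 1:3) {
    fw <- measure_fwhm(vol, loc, axis = ax)
    expect_equal(fw, 2 * sig * sqrt(2 * log(2)), tolerance = 0.05)
    # intensity scaling leaves FWHM unchanged
    expect_equal(measure_fwhm(vol * 7.3, loc, axis = ax), fw)
  }
  # a peak sitting at the volume edge leaves a crossing unbracketed
  vedge <- array(0, c(9, 9, 9))
  for (i in 1:9) vedge[i, 5, 5] <- exp(-(i - 1)^2 / (2 * 2^2))
  expect_warning(res <- measure_fwhm(vedge, matrix(c(1, 5, 5), 1), axis = 1))
  expect_true(is.na(res))
})

test_that("the Gaussian-beam parameters are recovered from bead stacks", {
  tru <- c(alpha = 2, beta = 0.05)
  m <- lsfm_psf_model(tru[1], tru[2])
  mb <- make_bead_volume(m, 10, c(48, 32, 24), seed = 9, min_separation = 10)
  fit <- fit_lsfm_model(mb$volume)
  expect_lt(abs(fit$alpha - tru[1]) / tru[1], 0.10)
  expect_lt(abs(fit$beta - tru[2]) / tru[2], 0.20)
  # beta = 0 stacks fit back to (almost) zero
  m0 <- lsfm_psf_model(2, 0)
  mb0 <- make_bead_volume(m0, 10, c(48, 32, 24), seed = 12, min_separation = 10)
  fit0 <- fit_lsfm_model(mb0$volume)
  expect_lte(fit0$beta, 0.01)
  # 20 dB noise: within twice the noiseless tolerances
  mbn <- make_bead_volume(m, 10, c(48, 32, 24),
                          noise = noise_spec("gaussian", snr_db = 20, seed = 3),
                          seed = 9, min_separation = 10)
  fitn <- fit_lsfm_model(mbn$volume)
  expect_lt(abs(fitn$alpha - tru[1]) / tru[1], 0.20)
  expect_lt(abs(fitn$beta - tru[2]) / tru[2], 0.40)
})
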