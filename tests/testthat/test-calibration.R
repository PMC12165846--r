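# Calibration: source detection, optical-center estimation and the
# Seidel coefficient fit.

test_that("well-separated synthetic sources are all detected within 1 px", {
  og <- optical_grid(64)
  co <- seidel_coefficients(sphere = 0.5, coma = 0.3)
  mc <- make_calibration_image(co, J = 15, og, seed = 21,
                               min_separation = 12, margin = 7)
  det <- detect_point_sources(mc$image_clean, min_separation = 8)
  expect_equal(nrow(det), 15)
  # match each apparent peak to a detection
  for (j in seq_len(15)) {
    d <- sqrt((det$row - mc$truth$peak_row[j])^2 +
              (det$col - mc$truth$peak_col[j])^2)
    expect_lt(min(d), 1)
  }
})

test_that("degenerate detection inputs follow their contracts", {
  expect_equal(nrow(detect_point_sources(matrix(0, 32, 32))), 0)
  # two sources closer than min_separation: brighter one kept, warning
  img <- matrix(0, 33, 33)
  img[15, 15] <- 1
  img[15, 19] <- 0.6
  expect_warning(det <- detect_point_sources(img, min_separation = 8,
                                             threshold_sigmas = 3),
                 "min_separation")
  expect_equal(nrow(det), 1)
  # centroid refinement is pulled slightly toward the fainter neighbour
  expect_lt(sqrt((det$row[1] - 15)^2 + (det$col[1] - 15)^2), 2)
})

test_that("the optical center is recovered within 2 px", {
  og <- optical_grid(64)
  co <- seidel_coefficients(sphere = 1, field_curvature = 1)
  # the 180-degree correlation needs enough beads for the self-pair peak
  # to dominate accidental pairings
  errs <- sapply(1:3, function(s) {
    mc <- make_calibration_image(co, J = 40, og, seed = s,
                                 min_separation = 6)
    max(abs(estimate_optical_center(mc$image_clean) - c(32.5, 32.5)))
  })
  expect_lt(median(errs), 2)
  expect_lt(max(errs), 4)
  # image symmetric about a shifted center
  N <- 64
  cs <- c(32.5 + 5, 32.5 - 3)
  img <- outer(1:N, 1:N, function(r, c)
    exp(-((r - cs[1])^2 + (c - cs[2])^2) / 60) +
    0.5 * exp(-(sqrt((r - cs[1])^2 + (c - cs[2])^2) - 12)^2 / 8))
  ctr2 <- estimate_optical_center(img)
  expect_lt(max(abs(ctr2 - cs)), 2)
  expect_error(estimate_optical_center(matrix(1, 32, 32)))
})

test_that("a diffraction-limited calibration image fits to zero aberrations", {
  og <- optical_grid(64)
  mc <- make_calibration_image(seidel_coefficients(), J = 8, og, seed = 3)
  fit <- fit_seidel(mc$cal, og, cfg = solver_config(max_iters = 60,
                                                    step_size = 0.05))
  expect_lt(max(abs(unclass(fit$coefficients))), 0.05)
})

test_that("known aberrations are recovered from a noiseless bead image", {
  og <- optical_grid(64)
  for (s in 1:2) {
    co <- sample_seidel_coefficients(1, seed = 40 + s)[[1]]
    mc <- make_calibration_image(co, J = 10, og, seed = 60 + s)
    fit <- fit_seidel(mc$cal, og, cfg = solver_config(max_iters = 100,
                                                      step_size = 0.05))
    expect_lt(max(abs(unclass(fit$coefficients) - unclass(co))), 0.05)
    expect_lt(utils::tail(fit$loss_trace, 1), fit$loss_trace[1])
  }
})

test_that("fitting is equivariant to rotating the calibration image", {
  og <- optical_grid(64)
  co <- as_seidel(c(1, 0.8, 0.6, 0.5, 0.4))
  mc <- make_calibration_image(co, J = 8, og, seed = 17)
  fit0 <- fit_seidel(mc$cal, og, cfg = solver_config(max_iters = 80,
                                                     step_size = 0.05))
  # rotate sources by 90 degrees about the center (exact on the grid)
  ctr <- 32.5
  src <- mc$cal$sources
  rot <- data.frame(row = ctr + (src$col - ctr),
                    col = ctr - (src$row - ctr))
  img_rot <- rot90o(mc$cal$image)
  cal_rot <- calibration_image(img_rot, rot)
  fit90 <- fit_seidel(cal_rot, og, cfg = solver_config(max_iters = 80,
                                                       step_size = 0.05))
  expect_lt(max(abs(unclass(fit90$coefficients) - unclass(fit0$coefficients))),
            0.05)
})

test_that("fitting on noisy data denoises the PSFs", {
  og <- optical_grid(64)
  co <- as_seidel(c(1.5, 1, 0.8, 1.2, 0.5))
  snr <- -20
  mc <- make_calibration_image(co, J = 10, og,
                               noise = noise_spec("gaussian", snr_db = snr,
                                                  seed = 77),
                               seed = 31)
  fit <- fit_seidel(mc$cal, og, cfg = solver_config(max_iters = 80,
                                                    step_size = 0.05))
  # PSFs regenerated from the fit are closer to the clean truth than the
  # raw noisy image regions are
  src <- mc$cal$sources
  err_fit <- err_raw <- numeric(nrow(src))
  for (j in seq_len(nrow(src))) {
    tru <- ringdeconv:::psf_field_model(co, src$radius[j], src$theta[j], og,
                                        gradients = FALSE)$psf
    tru <- tru / sqrt(sum(tru^2))
    mod <- ringdeconv:::psf_field_model(fit$coefficients, src$radius[j],
                                        src$theta[j], og,
                                        gradients = FALSE)$psf
    mod <- mod / sqrt(sum(mod^2))
    # raw observation around this source, normalized the same way
    cr <- round(src$row[j]); cc <- round(src$col[j])
    h <- 10
    ri <- max(1, cr - h):min(64, cr + h); ci <- max(1, cc - h):min(64, cc + h)
    raw <- mc$cal$image[ri, ci]
    tr2 <- (mc$image_clean / mc$truth$amplitude[j])[ri, ci]
    err_fit[j] <- rel_l2(mod, tru)
    err_raw[j] <- rel_l2(raw / max(sqrt(sum(raw^2)), 1e-300),
                         tr2 / max(sqrt(sum(tr2^2)), 1e-300))
  }
  expect_lt(median(err_fit), median(err_raw))
})

test_that("on-axis-only and empty source tables are rejected or flagged", {
  og <- optical_grid(32)
  img <- render_psf(seidel_coefficients(sphere = 1), 0, 0, og)
  cal0 <- calibration_image(img, data.frame(row = numeric(0), col = numeric(0)))
  expect_error(fit_seidel(cal0, og))
  cal1 <- calibration_image(img, data.frame(row = 16.5, col = 16.5))
  expect_warning(fit_seidel(cal1, og,
                            cfg = solver_config(max_iters = 5,
                                                step_size = 0.05),
                            n_starts = 1, init = "zeros"),
                 "on-axis")
})
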