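# File I/O: TIFF images and volumes, coefficient JSON, YAML run
# configuration, and provenance records.

#' Read a TIFF image or volume
#'
#' Single-page TIFFs load as a matrix; multi-page TIFFs load as a 3D
#' array with pages along the third (axial) dimension.  RGB input is
#' rejected: multicolor data should be split into channels and each
#' deblurred independently upstream.
#'
#' @param path file path (`.tif`/`.tiff`).
#' @return numeric matrix or 3D array (float, native scale).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!grepl("\\.tiff?$", path, ignore.case = TRUE))
    stop("unsupported format (expected .tif/.tiff): ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(dim(pages[[1]])) == 3)
    stop("RGB input not supported: extract a single channel first ",
         "(multicolor data are deblurred channel by channel)")
  if (length(pages) == 1) return(pages[[1]])
  arr <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  arr
}

#' Write a TIFF image or volume
#'
#' Matrices are written as single-page 32-bit float TIFF; 3D arrays as
#' multi-page (third dimension = pages).  Round-trip through
#' [read_image] is lossless at float32 precision.
#'
#' @param x numeric matrix or 3D array.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(x, path) {
  if (length(dim(x)) == 3) {
    pages <- lapply(seq_len(dim(x)[3]), function(k) x[, , k])
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  } else {
    tiff::writeTIFF(x, path, bits.per.sample = 32L)
  }
  invisible(path)
}

#' Read Seidel coefficients from JSON
#'
#' @param path JSON file with keys `sphere`, `coma`, `astigmatism`,
#'   `field_curvature`, `distortion` (floats, waves).
#' @return [seidel_coefficients].
#' @export
read_seidel_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("sphere", "coma", "astigmatism", "field_curvature", "distortion")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("coefficient file lacks keys: ", paste(missing, collapse = ", "))
  do.call(seidel_coefficients, as.list(vapply(x[need], as.numeric, numeric(1))))
}

#' Write Seidel coefficients to JSON
#'
#' @param coeffs [seidel_coefficients].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_seidel_json <- function(coeffs, path) {
  coeffs <- as_seidel(coeffs)
  jsonlite::write_json(as.list(unclass(coeffs)), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a PSF stack as multi-page TIFF with a JSON radius sidecar
#'
#' @param h a [radial_psf_stack].
#' @param path TIFF path; the sidecar is written at `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_psf_stack <- function(h, path) {
  stopifnot(inherits(h, "radial_psf_stack"))
  arr <- array(0, c(dim(h$psfs[[1]]), length(h$psfs)))
  for (k in seq_along(h$psfs)) arr[, , k] <- h$psfs[[k]]
  # scale into [0,1] for TIFF portability; scale recorded in the sidecar
  sc <- max(arr)
  write_image(arr / sc, path)
  jsonlite::write_json(list(radii = h$radii, image_N = h$image_N, scale = sc),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a PSF stack written by [write_psf_stack]
#'
#' @param path TIFF path with `<path>.json` sidecar.
#' @return [radial_psf_stack].
#' @export
read_psf_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  arr <- read_image(path) * (meta$scale %||% 1)
  psfs <- lapply(seq_len(dim(arr)[3]), function(k) arr[, , k])
  radial_psf_stack(psfs, meta$radii, image_N = meta$image_N)
}

#' Read a YAML run configuration
#'
#' @param path YAML file; recognized top-level keys include
#'   `image_size` (the image side length; a bare `N` key is also
#'   accepted but must be quoted, since YAML 1.1 reads `N` as a
#'   boolean), `pad_factor`, `max_iters`, `step_size`, `tv_weight`,
#'   `nonneg`, `tol`, `seed`.
#' @return list with `grid` ([optical_grid]), `solver`
#'   ([solver_config]) and the raw config under `raw`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # YAML 1.1 turns an unquoted key `N` into boolean FALSE; recover it
  Nval <- cfg$image_size %||% cfg$N %||% cfg[["FALSE"]]
  grid <- if (!is.null(Nval))
    optical_grid(Nval, pad_factor = cfg$pad_factor %||% 2)
  solver <- solver_config(
    max_iters = cfg$max_iters %||% 300,
    step_size = cfg$step_size %||% 0.1,
    tv_weight = cfg$tv_weight %||% 1e-4,
    nonneg = cfg$nonneg %||% TRUE,
    tol = cfg$tol %||% 1e-6,
    seed = cfg$seed %||% 1L)
  list(grid = grid, solver = solver, raw = cfg)
}

# Normalize an image to [0, 1] (loaded data are normalized before
# deblurring).
normalize_unit <- function(x) {
  rng <- range(x)
  if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) else x - rng[1]
}

# Hot-pixel removal: replace pixels more than k robust deviations above
# the local median with the median of their 3x3 neighbourhood.
remove_hot_pixels <- function(x, k = 8) {
  N <- nrow(x); Nc <- ncol(x)
  med <- x
  for (i in 2:(N - 1)) for (j in 2:(Nc - 1))
    med[i, j] <- stats::median(x[(i - 1):(i + 1), (j - 1):(j + 1)])
  dev <- x - med
  s <- stats::mad(dev)
  bad <- dev > k * max(s, 1e-12)
  x[bad] <- med[bad]
  x
}
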