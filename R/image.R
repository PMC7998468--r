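#' Grayscale radiograph container
#'
#' Bundles a pixel raster with the physical metadata every downstream
#' measurement needs: isotropic pixel spacing in mm and the anatomical
#' direction of the column axis. Rows run distal-ward (femur at the top,
#' tibia at the bottom of a lateral knee view); columns run
#' anterior--posterior, with `anterior` saying which way.
#'
#' Physical coordinates are mm, with `origin_mm` giving the position of the
#' centre of pixel `[1, 1]`; down-sampling shifts the origin so that mm
#' coordinates stay comparable across resolutions.
#'
#' @param pixels numeric matrix of gray values (finite).
#' @param spacing_mm isotropic pixel spacing in mm per pixel (> 0).
#' @param anterior `"+col"` if increasing column index moves anteriorly,
#'   `"-col"` otherwise.
#' @param laterality `"left"`, `"right"` or `"unknown"`.
#' @param origin_mm length-2 numeric, mm coordinate (x, y) of pixel (1, 1).
#' @return An object of class `image2d`.
#' @export
image2d <- function(pixels, spacing_mm, anterior = "+col",
                    laterality = "unknown", origin_mm = c(0, 0)) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("'pixels' must be a numeric matrix")
  if (!all(is.finite(pixels))) stop("'pixels' must be finite")
  stopifnot_scalar(spacing_mm, "spacing_mm", positive = TRUE)
  anterior <- match.arg(anterior, c("+col", "-col"))
  laterality <- match.arg(laterality, c("unknown", "left", "right"))
  structure(
    list(pixels = pixels, spacing_mm = spacing_mm, anterior = anterior,
         laterality = laterality, origin_mm = as.numeric(origin_mm)),
    class = "image2d")
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("<image2d> %d x %d px, %.4g mm/px, anterior %s, range [%.4g, %.4g]\n",
              nrow(x$pixels), ncol(x$pixels), x$spacing_mm, x$anterior,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
plot.image2d <- function(x, ...) {
  px <- x$pixels
  rng <- range(px)
  if (diff(rng) == 0) rng <- rng + c(0, 1)
  graphics::image(t(px[nrow(px):1, ]), col = grDevices::gray.colors(256),
                  zlim = rng, axes = FALSE, asp = nrow(px) / ncol(px), ...)
  invisible(x)
}

# mm coordinate of fractional pixel positions and the reverse
px_to_mm <- function(img, row, col) {
  cbind(img$origin_mm[1] + (col - 1) * img$spacing_mm,
        img$origin_mm[2] + (row - 1) * img$spacing_mm)
}
mm_to_px <- function(img, x, y) {
  cbind(row = (y - img$origin_mm[2]) / img$spacing_mm + 1,
        col = (x - img$origin_mm[1]) / img$spacing_mm + 1)
}

# Unit anterior direction of an image2d in the mm frame.
anterior_vec <- function(img_or_dir) {
  a <- if (is.character(img_or_dir)) img_or_dir else img_or_dir$anterior
  if (a == "+col") c(1, 0) else c(-1, 0)
}

gaussian_kernel_1d <- function(sigma_px) {
  r <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_px^2))
  k / sum(k)
}

# Separable Gaussian convolution with replicate padding.
gaussian_smooth <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  k <- gaussian_kernel_1d(sigma_px)
  r <- (length(k) - 1L) / 2L
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (j in seq_along(k)) {          # along columns
    cols <- pmin(pmax(seq_len(nc) + (j - r - 1L), 1L), nc)
    out <- out + k[j] * m[, cols, drop = FALSE]
  }
  m2 <- matrix(0, nr, nc)
  for (j in seq_along(k)) {          # along rows
    rows <- pmin(pmax(seq_len(nr) + (j - r - 1L), 1L), nr)
    m2 <- m2 + k[j] * out[rows, , drop = FALSE]
  }
  m2
}

#' Down-sample and smooth a radiograph
#'
#' Working-resolution preparation for segmentation: block-mean down-sampling
#' by an integer factor (pixel spacing is multiplied by the factor and the
#' mm origin shifted to the new pixel centres) followed by Gaussian
#' smoothing, which removes high-frequency noise while keeping the bone
#' edges localized.
#'
#' @param img an [image2d].
#' @param downsample_factor integer >= 1; 1 leaves the raster unchanged.
#' @param sigma_px Gaussian standard deviation in *output* pixels; 0 skips
#'   smoothing.
#' @return An [image2d] at the working resolution.
#' @export
preprocess <- function(img, downsample_factor = 2L, sigma_px = 1.5) {
  stopifnot(inherits(img, "image2d"))
  f <- as.integer(downsample_factor)
  if (f < 1L) stop("'downsample_factor' must be >= 1")
  if (sigma_px < 0) stop("'sigma_px' must be >= 0")
  px <- img$pixels
  if (f > nrow(px) || f > ncol(px))
    stop("'downsample_factor' larger than the image")
  origin <- img$origin_mm
  if (f > 1L) {
    nr <- nrow(px) %/% f; nc <- ncol(px) %/% f
    px <- px[seq_len(nr * f), seq_len(nc * f), drop = FALSE]
    # block mean: average f x f cells
    px <- .colsum_blocks(.rowsum_blocks(px, f), f) / (f * f)
    origin <- origin + (f - 1) / 2 * img$spacing_mm
  }
  px <- gaussian_smooth(px, sigma_px)
  image2d(px, spacing_mm = img$spacing_mm * f, anterior = img$anterior,
          laterality = img$laterality, origin_mm = origin)
}

# sum consecutive groups of f rows / of f columns
.rowsum_blocks <- function(m, f) {
  g <- rep(seq_len(nrow(m) %/% f), each = f)
  rowsum(m, g, reorder = TRUE)
}
.colsum_blocks <- function(m, f) {
  t(.rowsum_blocks(t(m), f))
}

#' Read a radiograph with its metadata sidecar
#'
#' Reads a PNG (or TIFF, if the `tiff` package is installed) raster and a
#' YAML sidecar `<path>.yaml` providing `pixel_spacing_mm` and optionally
#' `anterior_direction` and `laterality`. Images without a known pixel
#' spacing are rejected: every measurement downstream is in mm and guessing
#' the scale would silently corrupt them.
#'
#' @param path image file path.
#' @param pixel_spacing_mm spacing override when no sidecar exists.
#' @param anterior,laterality metadata overrides.
#' @return An [image2d].
#' @export
read_image2d <- function(path, pixel_spacing_mm = NULL, anterior = NULL,
                         laterality = NULL) {
  if (!file.exists(path)) stop(sprintf("image file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    stop(sprintf("unsupported image format '%s' (use PNG or TIFF)", ext)))
  if (length(dim(raw)) == 3L) raw <- raw[, , 1]    # first channel
  side <- paste0(path, ".yaml")
  meta <- if (file.exists(side)) yaml::read_yaml(side) else list()
  spacing <- pixel_spacing_mm %||% meta$pixel_spacing_mm
  if (is.null(spacing))
    stop(sprintf(
      "no pixel spacing for '%s': supply 'pixel_spacing_mm' or a sidecar %s",
      path, side))
  scale <- meta$intensity_scale %||% 1
  image2d(raw * scale, spacing_mm = spacing,
          anterior = anterior %||% meta$anterior_direction %||% "+col",
          laterality = laterality %||% meta$laterality %||% "unknown")
}

#' Write a radiograph as 16-bit PNG plus a YAML sidecar
#'
#' @param img an [image2d].
#' @param path output PNG path; the sidecar is written to `<path>.yaml`.
#' @param intensity_scale gray value that maps to full white; defaults to a
#'   small headroom above the image maximum so values round-trip.
#' @return `path`, invisibly.
#' @export
write_image2d <- function(img, path, intensity_scale = NULL) {
  stopifnot(inherits(img, "image2d"))
  if (is.null(intensity_scale)) {
    m <- max(img$pixels)
    intensity_scale <- if (m <= 0) 1 else m
  }
  px <- pmin(pmax(img$pixels / intensity_scale, 0), 1)
  png::writePNG(px, target = path, dpi = 25.4 / img$spacing_mm)
  yaml::write_yaml(
    list(pixel_spacing_mm = img$spacing_mm,
         anterior_direction = img$anterior,
         laterality = img$laterality,
         intensity_scale = intensity_scale),
    paste0(path, ".yaml"))
  invisible(path)
}
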