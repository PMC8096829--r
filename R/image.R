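# Raster helpers shared by the simulator, augmentations and the pipeline.
# Images are plain numeric matrices in [0, 1], rows = y (top-down), cols = x.
# EBImage stores images transposed (first dimension = x), so every call is
# wrapped with a transpose on the way in and out.

#' Read a grayscale image
#'
#' Reads an 8- or 16-bit PNG into a `[0, 1]` intensity matrix (rows = y).
#' Color images are converted to grayscale by channel averaging.
#'
#' @param path PNG file path.
#' @export
read_image <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- apply(a[, , 1:min(3L, dim(a)[3L]), drop = FALSE], c(1, 2), mean)
  a
}

#' Write a grayscale image as PNG
#' @param image numeric matrix in `[0, 1]`.
#' @param path output path.
#' @export
write_image <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' Resize an intensity matrix
#'
#' Bilinear resampling to `width` x `height` pixels; the aspect ratio is not
#' preserved (callers undo anisotropy through [crop_transform()]s).
#'
#' @param image numeric matrix.
#' @param width,height output size in pixels.
#' @export
resize_image <- function(image, width, height) {
  out <- EBImage::resize(EBImage::Image(t(image)), w = width, h = height,
                         filter = "bilinear")
  t(out@.Data)
}

# Gaussian blur with a brush that never exceeds the image.
blur_image <- function(image, sigma) {
  if (sigma <= 0) return(image)
  size <- 2L * as.integer(ceiling(2 * sigma)) + 1L
  size <- min(size, nrow(image) - !(nrow(image) %% 2), ncol(image) - !(ncol(image) %% 2))
  if (size < 3L) return(image)
  brush <- EBImage::makeBrush(size, shape = "Gaussian", sigma = sigma)
  t(EBImage::filter2(EBImage::Image(t(image)), brush,
                     boundary = "replicate")@.Data)
}

# Sample `image` at continuous pixel coordinates (0-based centers) with
# bilinear interpolation; out-of-canvas samples take `fill`.
# src_x, src_y: matrices of the same shape as the output.
warp_bilinear <- function(image, src_x, src_y, fill = 0) {
  h <- nrow(image); w <- ncol(image)
  x0 <- floor(src_x); y0 <- floor(src_y)
  fx <- src_x - x0; fy <- src_y - y0
  pick <- function(xi, yi) {
    ok <- xi >= 0 & xi <= (w - 1L) & yi >= 0 & yi <= (h - 1L)
    v <- matrix(fill, nrow(src_x), ncol(src_x))
    v[ok] <- image[cbind(yi[ok] + 1L, xi[ok] + 1L)]
    v
  }
  (1 - fx) * (1 - fy) * pick(x0, y0) +
    fx * (1 - fy) * pick(x0 + 1, y0) +
    (1 - fx) * fy * pick(x0, y0 + 1) +
    fx * fy * pick(x0 + 1, y0 + 1)
}

# Interpolate a field (matrix) at scattered 0-based points; n x 2 input.
interp_field <- function(field, points) {
  as.vector(warp_bilinear(field,
                          matrix(points[, 1L], nrow = 1L),
                          matrix(points[, 2L], nrow = 1L)))
}

#' Rescale image intensities to the unit interval
#'
#' `mode = "depth"` divides by the maximum representable value of the stated
#' bit depth (no-op for images already in `[0, 1]`); `mode = "minmax"`
#' stretches the observed range. A constant image under min-max maps to all
#' zeros with a warning.
#'
#' @param image numeric matrix.
#' @param mode `"depth"` or `"minmax"`.
#' @param bit_depth integer bit depth used by `"depth"` when the image holds
#'   raw integer counts; `NULL` (default) auto-detects 8 vs 16 bit from the
#'   maximum, and leaves `[0, 1]` data untouched.
#' @export
normalize_intensity <- function(image, mode = c("depth", "minmax"),
                                bit_depth = NULL) {
  mode <- match.arg(mode)
  if (mode == "minmax") {
    r <- range(image)
    if (diff(r) <= 0) {
      warning("constant image under min-max normalization; returning zeros")
      return(image * 0)
    }
    return((image - r[1L]) / diff(r))
  }
  mx <- if (!is.null(bit_depth)) 2^bit_depth - 1
        else if (max(image) <= 1) 1
        else if (max(image) <= 255) 255
        else 65535
  pmin(pmax(image / mx, 0), 1)
}
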