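#' Extended bounding box around a corner set
#'
#' Builds the tight axis-aligned box around the valid corners, grows each
#' side length by `extension` (half of the added span on each side), then
#' clips to the image. This is the crop the per-vertebra refinement network
#' sees; the default 70% extension leaves generous context around the
#' vertebral body on both axes.
#'
#' @param corners a [corner_set()] or a k x 2 matrix of points.
#' @param extension fraction of each span to add (default 0.7).
#' @param image_size `c(width, height)` in pixels, used for clipping.
#' @return named numeric vector `c(x_min, y_min, x_max, y_max)`.
#' @examples
#' pts <- rbind(c(10, 20), c(30, 20), c(10, 60), c(30, 60))
#' extended_bbox(pts, 0, c(100, 100))    # tight: 10 20 30 60
#' extended_bbox(pts, 0.7, c(500, 500))  # 3 6 37 74
#' @export
extended_bbox <- function(corners, extension = 0.7, image_size) {
  pts <- if (inherits(corners, "corner_set")) valid_points(corners) else as.matrix(corners)
  if (nrow(pts) < 2L) stop("need at least 2 valid corners for a bounding box",
                           call. = FALSE)
  if (extension < 0) stop("'extension' must be >= 0", call. = FALSE)
  xr <- range(pts[, 1L]); yr <- range(pts[, 2L])
  if (diff(xr) <= 0 || diff(yr) <= 0) {
    stop("degenerate corner set: zero extent along one axis", call. = FALSE)
  }
  mx <- extension / 2 * diff(xr)
  my <- extension / 2 * diff(yr)
  box <- c(x_min = xr[1L] - mx, y_min = yr[1L] - my,
           x_max = xr[2L] + mx, y_max = yr[2L] + my)
  clip_bbox(box, image_size)
}

clip_bbox <- function(box, image_size) {
  box[c("x_min", "x_max")] <- pmin(pmax(box[c("x_min", "x_max")], 0), image_size[1L] - 1)
  box[c("y_min", "y_max")] <- pmin(pmax(box[c("y_min", "y_max")], 0), image_size[2L] - 1)
  if (box["x_min"] >= box["x_max"] || box["y_min"] >= box["y_max"]) {
    stop("bounding box collapsed after clipping", call. = FALSE)
  }
  box
}

#' Invertible crop-and-resize transform
#'
#' A `crop_transform` records the mapping between original-image pixels and
#' the pixels of a cropped, resized view: `p_out = (p - offset) * scale`,
#' `p_orig = p_out / scale + offset`. It is the bookkeeping that lets corner
#' coordinates predicted on a per-vertebra crop be mapped back to the
#' original radiograph.
#'
#' @param offset `c(x, y)` of the crop's top-left corner in the original frame.
#' @param scale `c(sx, sy)` crop-to-output resize factors.
#' @param output_size `c(width, height)` of the output view.
#' @export
crop_transform <- function(offset, scale, output_size) {
  stopifnot(length(offset) == 2L, length(scale) == 2L, all(scale > 0),
            length(output_size) == 2L, all(output_size >= 1))
  structure(list(offset = as.numeric(offset), scale = as.numeric(scale),
                 output_size = as.numeric(output_size)),
            class = "crop_transform")
}

#' @export
print.crop_transform <- function(x, ...) {
  cat(sprintf("<crop_transform> offset (%.2f, %.2f) scale (%.4f, %.4f) -> %dx%d\n",
              x$offset[1], x$offset[2], x$scale[1], x$scale[2],
              x$output_size[1], x$output_size[2]))
  invisible(x)
}

#' Map original-frame points into a transform's output frame
#' @param points n x 2 matrix (or length-2 vector) in original pixels.
#' @param transform a [crop_transform()].
#' @export
to_cropped <- function(points, transform) {
  p <- rbind2mat(points)
  cbind((p[, 1L] - transform$offset[1L]) * transform$scale[1L],
        (p[, 2L] - transform$offset[2L]) * transform$scale[2L])
}

#' Map output-frame points back to the original frame
#' @inheritParams to_cropped
#' @examples
#' tf <- crop_transform(offset = c(10, 10), scale = c(2, 2), output_size = c(64, 64))
#' to_original(c(100, 40), tf)  # (60, 30)
#' @export
to_original <- function(points, transform) {
  p <- rbind2mat(points)
  cbind(p[, 1L] / transform$scale[1L] + transform$offset[1L],
        p[, 2L] / transform$scale[2L] + transform$offset[2L])
}

rbind2mat <- function(points) {
  if (is.null(dim(points))) matrix(as.numeric(points), ncol = 2L)
  else as.matrix(points)
}

#' Crop a box out of an image and resize it
#'
#' The box is snapped to whole pixels (floor/ceil), the sub-image extracted
#' and resampled to `output_size` with bilinear interpolation. The aspect
#' ratio is deliberately not preserved: both networks consume fixed square
#' inputs, and anisotropic scaling is undone exactly by the returned
#' transform. Returns the resized view together with its [crop_transform()].
#'
#' @param image numeric matrix (rows = y).
#' @param box `c(x_min, y_min, x_max, y_max)` inside the image.
#' @param output_size `c(width, height)` in pixels.
#' @return list with `image` (output_size matrix) and `transform`.
#' @export
crop_resize <- function(image, box, output_size) {
  if (any(output_size < 1)) stop("'output_size' must be positive", call. = FALSE)
  x0 <- max(0L, floor(box[["x_min"]])); y0 <- max(0L, floor(box[["y_min"]]))
  x1 <- min(ncol(image) - 1L, ceiling(box[["x_max"]]))
  y1 <- min(nrow(image) - 1L, ceiling(box[["y_max"]]))
  if (x1 <= x0 || y1 <= y0) stop("box does not cover at least 2x2 pixels", call. = FALSE)
  sub <- image[(y0 + 1L):(y1 + 1L), (x0 + 1L):(x1 + 1L), drop = FALSE]
  cw <- x1 - x0 + 1L; ch <- y1 - y0 + 1L
  out <- resize_image(sub, output_size[1L], output_size[2L])
  list(image = out,
       transform = crop_transform(offset = c(x0, y0),
                                  scale = c(output_size[1L] / cw,
                                            output_size[2L] / ch),
                                  output_size = output_size))
}

#' Unsigned angle between two endplate lines
#'
#' Computes the acute angle between the line through `line_a`'s two points
#' and the line through `line_b`'s, in degrees within `[0, 90]`. Direction
#' vectors are used rather than slope coefficients, so vertical endplates
#' are handled without special cases.
#'
#' @param line_a,line_b 2 x 2 matrices, one point per row (x, y).
#' @return angle in degrees.
#' @examples
#' endplate_angle(rbind(c(0, 0), c(10, 0)), rbind(c(0, 0), c(10, 10)))  # 45
#' @export
endplate_angle <- function(line_a, line_b) {
  u <- line_dir(line_a); v <- line_dir(line_b)
  dotp <- abs(sum(u * v))
  crossp <- abs(u[1L] * v[2L] - u[2L] * v[1L])
  unname(atan2(crossp, dotp) * 180 / pi)
}

line_dir <- function(line) {
  line <- as.matrix(line)
  d <- line[2L, ] - line[1L, ]
  n <- sqrt(sum(d^2))
  if (n < .Machine$double.eps) {
    stop("degenerate line: coincident points", call. = FALSE)
  }
  d / n
}

#' Sacral slope from the S1 upper endplate
#'
#' Unsigned angle of the S1 upper endplate line to the horizontal, in
#' degrees within `[0, 90]`.
#'
#' @param s1_upper 2 x 2 matrix, the two upper-endplate points of S1.
#' @export
sacral_slope <- function(s1_upper) {
  u <- line_dir(s1_upper)
  unname(atan2(abs(u[2L]), abs(u[1L])) * 180 / pi)
}

#' Spinopelvic angles from a landmark map
#'
#' Derives the three clinical angles from corner landmarks:
#' L1-L5 lordosis (L1 upper vs L5 lower endplate), L1-S1 lordosis
#' (L1 upper vs S1 upper endplate) and sacral slope (S1 upper endplate vs
#' horizontal). Angles are unsigned in `[0, 90]` degrees; an angle whose
#' landmarks are missing is reported as `NA`.
#'
#' @param landmarks named list of [corner_set()] keyed by level.
#' @return named list `L1_L5`, `L1_S1`, `SS` (degrees or `NA`), class
#'   `angle_report`.
#' @export
angles_from_corners <- function(landmarks) {
  upper <- function(lev) {
    cs <- landmarks[[lev]]
    if (is.null(cs) || !all(cs$valid[1:2])) return(NULL)
    cs$points[1:2, , drop = FALSE]
  }
  lower <- function(lev) {
    cs <- landmarks[[lev]]
    if (is.null(cs) || !all(cs$valid[3:4])) return(NULL)
    cs$points[3:4, , drop = FALSE]
  }
  l1u <- upper("L1"); l5l <- lower("L5"); s1u <- upper("S1")
  rep_na <- function(a, b, f) if (is.null(a) || is.null(b)) NA_real_ else f(a, b)
  structure(list(
    L1_L5 = rep_na(l1u, l5l, endplate_angle),
    L1_S1 = rep_na(l1u, s1u, endplate_angle),
    SS = if (is.null(s1u)) NA_real_ else sacral_slope(s1u)
  ), class = "angle_report")
}

#' @export
print.angle_report <- function(x, ...) {
  fmt <- function(a) if (is.na(a)) "  --  " else sprintf("%5.1f°", a)
  cat(sprintf("<angle_report> L1-L5 %s  L1-S1 %s  SS %s\n",
              fmt(x$L1_L5), fmt(x$L1_S1), fmt(x$SS)))
  invisible(x)
}
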