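#' Differentiable spatial-to-numerical transform (DSNT)
#'
#' The localization networks end in spatial heatmaps, one channel per corner
#' landmark. A DSNT head turns each heatmap into a coordinate by (1)
#' normalizing the channel into a probability distribution with a spatial
#' softmax and (2) taking the expectation of a fixed coordinate grid spanning
#' `[-1, 1]` under that distribution. Both steps are differentiable, so the
#' network can be trained end-to-end with a plain Euclidean loss on
#' coordinates, and the expectation can never leave `[-1, 1]`.
#'
#' @name dsnt
NULL

#' Spatial softmax normalization of one heatmap channel
#'
#' @param raw numeric matrix of unnormalized scores (any finite values).
#' @return matrix of the same shape: strictly positive, summing to 1.
#' @examples
#' normalize_heatmap(matrix(0, 3, 3))  # uniform 1/9
#' @rdname dsnt
#' @export
normalize_heatmap <- function(raw) {
  if (!all(is.finite(raw))) stop("heatmap contains non-finite values", call. = FALSE)
  e <- exp(raw - max(raw))
  e / sum(e)
}

#' Normalized coordinate of a grid cell
#'
#' Maps 0-based cell index `i` on an axis with `n` cells to
#' `(2 i + 1 - n) / n`, placing pixel centers strictly inside `(-1, 1)`.
#' Vectorized over `index`.
#'
#' @param index 0-based cell index (vectorized).
#' @param n number of cells along the axis.
#' @rdname dsnt
#' @export
grid_coordinate <- function(index, n) {
  if (any(index < 0 | index > n - 1)) stop("grid index out of range", call. = FALSE)
  (2 * index + 1 - n) / n
}

#' Coordinate expectation of a normalized heatmap channel
#'
#' @param channel matrix summing to 1 (see [normalize_heatmap()]); rows are
#'   y, columns are x.
#' @return `c(x, y)` in `[-1, 1]`.
#' @rdname dsnt
#' @export
dsnt_expect <- function(channel) {
  s <- sum(channel)
  if (abs(s - 1) > 1e-4) {
    stop(sprintf("heatmap channel not normalized (sum = %.6f)", s), call. = FALSE)
  }
  gx <- grid_coordinate(seq_len(ncol(channel)) - 1, ncol(channel))
  gy <- grid_coordinate(seq_len(nrow(channel)) - 1, nrow(channel))
  c(x = sum(colSums(channel) * gx), y = sum(rowSums(channel) * gy))
}

#' Masked mean Euclidean coordinate loss
#'
#' Training loss of both localization stages: the mean Euclidean distance
#' between predicted and target coordinates in normalized `[-1, 1]` space,
#' averaged over the masked-in points only. Vertebrae absent from an image
#' (and the masked lower corners of S1) contribute nothing — the annotation
#' carries no target there, so fabricating one would corrupt training.
#'
#' @param pred,target n x 2 numeric matrices of normalized coordinates (a
#'   24x4x2 or 1x4x2 block flattened to rows).
#' @param mask logical vector of length n; `NULL` means all valid.
#' @return scalar loss; if every point is masked out, 0 with attribute
#'   `empty_mask = TRUE` and a warning.
#' @rdname dsnt
#' @export
coord_loss <- function(pred, target, mask = NULL) {
  pred <- rbind2mat(pred); target <- rbind2mat(target)
  stopifnot(all(dim(pred) == dim(target)))
  if (is.null(mask)) mask <- rep(TRUE, nrow(pred))
  if (!any(mask)) {
    warning("coord_loss: all points masked out")
    return(structure(0, empty_mask = TRUE))
  }
  d <- sqrt(rowSums((pred[mask, , drop = FALSE] - target[mask, , drop = FALSE])^2))
  mean(d)
}

#' Convert normalized coordinates to pixel coordinates
#'
#' Inverse of the `[-1, 1]` normalization: `x_pix = (x_norm * w + w - 1) / 2`
#' (likewise for y with `h`), so that `denormalize(grid_coordinate(i, n))`
#' recovers the cell index `i` exactly.
#'
#' @param points n x 2 matrix (or length-2 vector) of normalized coordinates.
#' @param size `c(width, height)` of the pixel frame.
#' @return n x 2 matrix of 0-based pixel coordinates.
#' @rdname dsnt
#' @export
denormalize <- function(points, size) {
  p <- rbind2mat(points)
  cbind((p[, 1L] * size[1L] + size[1L] - 1) / 2,
        (p[, 2L] * size[2L] + size[2L] - 1) / 2)
}

#' Convert pixel coordinates to normalized coordinates
#'
#' Exact inverse of [denormalize()]: `x_norm = (2 x_pix + 1 - w) / w`.
#'
#' @inheritParams denormalize
#' @rdname dsnt
#' @export
normalize_coords <- function(points, size) {
  p <- rbind2mat(points)
  cbind((2 * p[, 1L] + 1 - size[1L]) / size[1L],
        (2 * p[, 2L] + 1 - size[2L]) / size[2L])
}
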