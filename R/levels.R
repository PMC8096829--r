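#' Spine levels and corner conventions
#'
#' The pipeline models the 24 vertebral levels from C2 down to S1. Levels are
#' identified by name ("C2".."C7", "T1".."T12", "L1".."L5", "S1") and by a
#' 0-based ordinal running cranial to caudal, which indexes the 24-way
#' presence vector and the 24 corner-heatmap blocks.
#'
#' @format `spine_levels()` returns a character vector of length 24 in
#'   anatomical order.
#' @export
spine_levels <- function() .SPINE_LEVELS

.SPINE_LEVELS <- c(paste0("C", 2:7), paste0("T", 1:12), paste0("L", 1:5), "S1")

#' Corner labels in canonical order
#'
#' Corners of a vertebral body are always stored in the fixed order
#' upper-anterior, upper-posterior, lower-anterior, lower-posterior
#' ("UA", "UP", "LA", "LP"). A fixed published order is what makes the four
#' DSNT corner channels comparable across images; anterior/posterior refer to
#' image content (anterior at larger x), so horizontal flips must swap the
#' anterior/posterior roles (see [random_rotate_flip()]).
#'
#' @export
corner_names <- function() c("UA", "UP", "LA", "LP")

#' Map level names to 0-based cranial-to-caudal ordinals and back
#'
#' @param level character vector of level names.
#' @param ordinal integer vector in 0..23.
#' @return `level_ordinal()` returns integers in 0..23; `ordinal_level()`
#'   returns level names.
#' @examples
#' level_ordinal("C2")  # 0
#' level_ordinal("S1")  # 23
#' ordinal_level(18:23) # "L1" .. "S1"
#' @export
level_ordinal <- function(level) {
  idx <- match(level, .SPINE_LEVELS)
  if (anyNA(idx)) {
    stop("unknown vertebral level(s): ",
         paste(level[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  idx - 1L
}

#' @rdname level_ordinal
#' @export
ordinal_level <- function(ordinal) {
  ordinal <- as.integer(ordinal)
  if (any(ordinal < 0L | ordinal > 23L)) {
    stop("ordinal out of range 0..23", call. = FALSE)
  }
  .SPINE_LEVELS[ordinal + 1L]
}

#' Contiguous run of levels between two endpoints (inclusive)
#'
#' @param from,to level names, `from` cranial to (or equal to) `to`.
#' @export
level_seq <- function(from, to) {
  a <- level_ordinal(from); b <- level_ordinal(to)
  if (a > b) stop("'from' must be cranial to 'to'", call. = FALSE)
  ordinal_level(a:b)
}

#' Construct a corner set
#'
#' A corner set holds the four corner landmarks of one vertebral body, in
#' pixel coordinates of the image it belongs to (0-based pixel centers,
#' origin top-left, x rightward, y downward), plus a validity mask. S1 has
#' only an upper endplate, so its canonical corner set has the two lower
#' corners masked out.
#'
#' @param points 4x2 numeric matrix (rows UA, UP, LA, LP; columns x, y).
#'   Rows masked invalid may be `NA`.
#' @param valid logical(4); defaults to the rows with complete finite
#'   coordinates.
#' @return An object of class `corner_set`.
#' @examples
#' cs <- corner_set(rbind(c(10, 5), c(30, 6), c(11, 25), c(31, 26)))
#' s1 <- corner_set(rbind(c(10, 5), c(30, 6), c(NA, NA), c(NA, NA)))
#' sum(s1$valid)  # 2
#' @export
corner_set <- function(points, valid = NULL) {
  points <- as.matrix(points)
  if (!is.numeric(points) || !all(dim(points) == c(4L, 2L))) {
    stop("'points' must be a 4x2 numeric matrix", call. = FALSE)
  }
  dimnames(points) <- list(corner_names(), c("x", "y"))
  if (is.null(valid)) {
    valid <- apply(points, 1L, function(p) all(is.finite(p)))
  }
  valid <- as.logical(valid)
  if (length(valid) != 4L || anyNA(valid)) {
    stop("'valid' must be logical(4) without NA", call. = FALSE)
  }
  ok <- points[valid, , drop = FALSE]
  if (length(ok) && (!all(is.finite(ok)) || any(ok < 0))) {
    stop("valid corners must have finite, non-negative coordinates",
         call. = FALSE)
  }
  structure(list(points = points, valid = valid), class = "corner_set")
}

#' @export
print.corner_set <- function(x, ...) {
  cat("<corner_set> ", sum(x$valid), "/4 valid corners\n", sep = "")
  print(round(x$points, 2))
  invisible(x)
}

#' Number of valid corners
#' @param cs a [corner_set()].
#' @export
n_valid_corners <- function(cs) sum(cs$valid)

#' Valid corner coordinates as a matrix
#' @param cs a [corner_set()].
#' @return k x 2 matrix of the valid points only.
#' @export
valid_points <- function(cs) cs$points[cs$valid, , drop = FALSE]

#' Construct an annotated image
#'
#' The unit flowing through the whole pipeline: a grayscale intensity matrix
#' in `[0, 1]` (rows = y, columns = x, origin top-left) together with the
#' per-level corner landmarks in that image's pixel frame.
#'
#' @param pixels numeric matrix in `[0, 1]`.
#' @param landmarks named list, names are level names, values [corner_set()]s.
#' @param image_id character scalar.
#' @return An object of class `annotated_image` with fields `pixels`,
#'   `landmarks`, `image_id`.
#' @export
annotated_image <- function(pixels, landmarks = list(), image_id = "img") {
  pixels <- as.matrix(pixels)
  stopifnot(is.numeric(pixels), nrow(pixels) >= 1, ncol(pixels) >= 1)
  if (length(landmarks)) {
    level_ordinal(names(landmarks))  # validates names
    bad <- !vapply(landmarks, inherits, logical(1), "corner_set")
    if (any(bad)) stop("all landmarks must be corner_set objects", call. = FALSE)
    landmarks <- landmarks[order(level_ordinal(names(landmarks)))]
  }
  structure(list(pixels = pixels, landmarks = landmarks,
                 image_id = as.character(image_id)),
            class = "annotated_image")
}

#' @export
print.annotated_image <- function(x, ...) {
  cat(sprintf("<annotated_image> '%s' %dx%d px, %d annotated level(s): %s\n",
              x$image_id, ncol(x$pixels), nrow(x$pixels), length(x$landmarks),
              paste(names(x$landmarks), collapse = " ")))
  invisible(x)
}

#' Image size of an annotated image as c(width, height)
#' @param img an [annotated_image()].
#' @export
image_size <- function(img) c(ncol(img$pixels), nrow(img$pixels))

#' Derive the 24-way presence vector from a landmark map
#'
#' Training target of the presence classifier: one flag per spine level,
#' true when the level carries at least two valid corner landmarks (the
#' minimum needed to define an endplate).
#'
#' @param landmarks named list of [corner_set()] keyed by level name.
#' @return named logical vector of length 24, names `spine_levels()`.
#' @examples
#' presence_from_landmarks(list())["L3"]  # FALSE
#' @export
presence_from_landmarks <- function(landmarks) {
  flags <- stats::setNames(rep(FALSE, 24L), .SPINE_LEVELS)
  if (length(landmarks)) {
    nv <- vapply(landmarks, n_valid_corners, integer(1))
    flags[names(landmarks)[nv >= 2L]] <- TRUE
  }
  flags
}
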