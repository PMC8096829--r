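#' Read corner annotations from CSV
#'
#' Parses the annotation dialect used throughout the package: a UTF-8 CSV
#' with header `image_id,level,corner,x,y`, one row per landmark, `level` in
#' C2..S1, `corner` in UA/UP/LA/LP, coordinates in original-image pixels.
#' Rows are validated individually so malformed input is reported with its
#' line number. If S1 arrives with four corners (some annotation tools store
#' them), its lower two are accepted but down-masked, since only the upper
#' endplate of S1 is anatomically defined.
#'
#' @param path path to an annotation CSV.
#' @return named list: `image_id` -> named list of [corner_set()] by level.
#' @seealso [write_annotations()] for the exact inverse.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines)) stop("empty annotation file (no header): ", path, call. = FALSE)
  header <- strsplit(lines[[1L]], ",", fixed = TRUE)[[1L]]
  if (!identical(header, c("image_id", "level", "corner", "x", "y"))) {
    stop("bad annotation header at line 1: expected 'image_id,level,corner,x,y'",
         call. = FALSE)
  }
  cn <- corner_names()
  # accumulate per (image, level): 4x2 coordinate matrix
  acc <- new.env(parent = emptyenv())
  seen <- new.env(parent = emptyenv())
  for (i in seq_along(lines)[-1L]) {
    line <- lines[[i]]
    if (!nzchar(line)) next
    f <- strsplit(line, ",", fixed = TRUE)[[1L]]
    if (length(f) != 5L) {
      stop(sprintf("malformed annotation row at line %d: expected 5 fields, got %d",
                   i, length(f)), call. = FALSE)
    }
    if (!f[[2L]] %in% .SPINE_LEVELS) {
      stop(sprintf("unknown vertebral level '%s' at line %d", f[[2L]], i),
           call. = FALSE)
    }
    ci <- match(f[[3L]], cn)
    if (is.na(ci)) {
      stop(sprintf("unknown corner '%s' at line %d (expected UA/UP/LA/LP)",
                   f[[3L]], i), call. = FALSE)
    }
    xy <- suppressWarnings(as.numeric(f[4:5]))
    if (anyNA(xy) || any(!is.finite(xy))) {
      stop(sprintf("non-numeric coordinates at line %d", i), call. = FALSE)
    }
    key <- paste(f[[1L]], f[[2L]], sep = "\r")
    dup <- paste(key, f[[3L]], sep = "\r")
    if (!is.null(seen[[dup]])) {
      stop(sprintf("duplicate record (image '%s', level %s, corner %s) at line %d",
                   f[[1L]], f[[2L]], f[[3L]], i), call. = FALSE)
    }
    seen[[dup]] <- TRUE
    m <- acc[[key]]
    if (is.null(m)) m <- matrix(NA_real_, 4L, 2L)
    m[ci, ] <- xy
    acc[[key]] <- m
  }
  out <- list()
  for (key in ls(acc)) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    id <- parts[[1L]]; lev <- parts[[2L]]
    m <- acc[[key]]
    valid <- stats::complete.cases(m)
    if (identical(lev, "S1")) valid[3:4] <- FALSE
    if (is.null(out[[id]])) out[[id]] <- list()
    out[[id]][[lev]] <- corner_set(m, valid)
  }
  if (!length(out)) return(list())
  # canonical ordering: image ids alphabetical, levels cranial->caudal
  out <- out[order(names(out))]
  lapply(out, function(lm) lm[order(level_ordinal(names(lm)))])
}

#' Write corner annotations to CSV
#'
#' Inverse of [read_annotations()]. Rows are emitted in canonical order
#' (image id, then level ordinal, then corner order UA/UP/LA/LP), only for
#' valid corners, with coordinates printed to 3 decimals, so that
#' write -> read -> write is byte-identical.
#'
#' @param landmarks named list: image_id -> named list of [corner_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(landmarks, path) {
  cn <- corner_names()
  rows <- character(0)
  for (id in sort(names(landmarks))) {
    lm <- landmarks[[id]]
    for (lev in names(lm)[order(level_ordinal(names(lm)))]) {
      cs <- lm[[lev]]
      for (ci in which(cs$valid)) {
        rows <- c(rows, sprintf("%s,%s,%s,%.3f,%.3f", id, lev, cn[[ci]],
                                cs$points[ci, 1L], cs$points[ci, 2L]))
      }
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("image_id,level,corner,x,y", rows), con, sep = "\n")
  invisible(path)
}

#' Landmark maps of a set of annotated images, keyed by image id
#'
#' Convenience for writing a simulated set with [write_annotations()].
#'
#' @param images list of [annotated_image()].
#' @export
landmark_map <- function(images) {
  stats::setNames(lapply(images, `[[`, "landmarks"),
                  vapply(images, `[[`, character(1), "image_id"))
}
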