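#' Training-time augmentation configuration
#'
#' All augmentations are coordinate-aware: the same geometric transform is
#' applied to pixels and landmarks, keeping the landmark/pixel
#' correspondence intact. The caudal crop emulates variable fields of view
#' by cutting the lower part of the image so that L5, L4 or L3 becomes the
#' most caudal visible vertebra; it is a training-only augmentation.
#'
#' @param rotation_range max absolute rotation in degrees (default 10; small
#'   rotations match the postural variability of clinical radiographs while
#'   keeping landmarks in-canvas).
#' @param flip_prob probability of a horizontal flip.
#' @param elastic_alpha displacement amplitude in pixels (0 disables).
#' @param elastic_sigma smoothness of the displacement field in pixels.
#' @param noise_sd additive Gaussian pixel noise (unit intensity scale).
#' @param caudal_crop_prob probability of attempting the caudal crop.
#' @param min_visible minimum number of vertebrae that must stay visible.
#' @param max_attempts rejection-sampling budget for constrained transforms.
#' @param oob_policy what to do when a rotation pushes landmarks off canvas:
#'   `"resample"` tries another angle, `"skip"` returns the input unchanged.
#' @param seed optional seed applied by each augmentation call.
#' @export
augment_config <- function(rotation_range = 10, flip_prob = 0.5,
                           elastic_alpha = 2, elastic_sigma = 8,
                           noise_sd = 0.02, caudal_crop_prob = 0.5,
                           min_visible = 3L, max_attempts = 50L,
                           oob_policy = c("resample", "skip"),
                           seed = NULL) {
  stopifnot(rotation_range >= 0, flip_prob >= 0, flip_prob <= 1,
            elastic_alpha >= 0, elastic_sigma > 0, noise_sd >= 0,
            caudal_crop_prob >= 0, caudal_crop_prob <= 1, min_visible >= 1)
  structure(list(rotation_range = rotation_range, flip_prob = flip_prob,
                 elastic_alpha = elastic_alpha, elastic_sigma = elastic_sigma,
                 noise_sd = noise_sd, caudal_crop_prob = caudal_crop_prob,
                 min_visible = as.integer(min_visible),
                 max_attempts = as.integer(max_attempts),
                 oob_policy = match.arg(oob_policy), seed = seed),
            class = "augment_config")
}

landmark_matrix <- function(img) {
  do.call(rbind, lapply(img$landmarks, valid_points))
}

#' Random caudal field-of-view crop
#'
#' With probability `caudal_crop_prob`, rejection-samples a cut height in
#' the lower half of the image such that (a) no vertebra is sliced by the
#' cut, (b) at least one vertebra is removed, (c) the most caudal remaining
#' vertebra is L3, L4 or L5, and (d) at least `min_visible` vertebrae
#' remain. Rows below the cut are removed and the landmarks of the removed
#' vertebrae dropped. If no admissible cut is found within `max_attempts`
#' tries, the input is returned unchanged.
#'
#' @param img an [annotated_image()].
#' @param config an [augment_config()].
#' @param seed optional integer seed.
#' @export
random_caudal_crop <- function(img, config = augment_config(), seed = config$seed) {
  with_seed(seed, {
    if (length(img$landmarks) < config$min_visible) {
      stop("image has fewer annotated vertebrae than 'min_visible'", call. = FALSE)
    }
    if (runif(1) >= config$caudal_crop_prob) return(img)
    h <- nrow(img$pixels)
    levels <- names(img$landmarks)
    ymin <- vapply(img$landmarks, function(cs) min(valid_points(cs)[, 2L]), numeric(1))
    ymax <- vapply(img$landmarks, function(cs) max(valid_points(cs)[, 2L]), numeric(1))
    for (attempt in seq_len(config$max_attempts)) {
      y_cut <- runif(1, h / 2, h - 1)
      sliced <- ymin < y_cut & ymax > y_cut
      if (any(sliced)) next
      keep <- ymax < y_cut
      if (!any(keep) || all(keep)) next       # must remove something
      kept <- levels[keep]
      caudal <- kept[which.max(level_ordinal(kept))]
      if (!caudal %in% c("L3", "L4", "L5")) next
      if (sum(keep) < config$min_visible) next
      rows <- seq_len(max(2L, as.integer(ceiling(y_cut))))
      return(annotated_image(img$pixels[rows, , drop = FALSE],
                             img$landmarks[keep], img$image_id))
    }
    img  # no admissible cut found: no-op
  })
}

# rotate 0-based points by theta (radians) about `ctr`: p' = R (p - c) + c
# with R = [[cos, -sin], [sin, cos]] applied to screen coordinates
rotate_points <- function(points, theta, ctr) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
  sweep(sweep(rbind2mat(points), 2L, ctr) %*% t(R), 2L, ctr, "+")
}

flip_corner_roles <- function(cs) {
  corner_set(cs$points[c(2L, 1L, 4L, 3L), , drop = FALSE],
             cs$valid[c(2L, 1L, 4L, 3L)])
}

transform_landmarks <- function(landmarks, f) {
  lapply(landmarks, function(cs) {
    pm <- cs$points
    if (any(cs$valid)) {
      pm[cs$valid, ] <- f(pm[cs$valid, , drop = FALSE])
    }
    corner_set(pm, cs$valid)
  })
}

#' Random rotation and horizontal flip
#'
#' Rotates pixels and landmarks by the same random angle about the image
#' center (convention: the point transform is `p' - c = R(theta) (p - c)`
#' with the standard rotation matrix applied to screen coordinates), and
#' horizontally flips with probability `flip_prob`. A flip swaps the
#' anterior/posterior corner roles within each endplate so that the fixed
#' corner-channel semantics stay consistent. If a rotation pushes any
#' landmark off the canvas the angle is resampled (or the sample skipped,
#' per `oob_policy`).
#'
#' @inheritParams random_caudal_crop
#' @export
random_rotate_flip <- function(img, config = augment_config(), seed = config$seed) {
  with_seed(seed, {
    h <- nrow(img$pixels); w <- ncol(img$pixels)
    ctr <- c((w - 1) / 2, (h - 1) / 2)
    do_flip <- runif(1) < config$flip_prob
    pixels <- img$pixels
    landmarks <- img$landmarks
    if (do_flip) {
      pixels <- pixels[, w:1, drop = FALSE]
      landmarks <- transform_landmarks(landmarks, function(p) {
        cbind((w - 1) - p[, 1L], p[, 2L])
      })
      landmarks <- lapply(landmarks, flip_corner_roles)
    }

    if (config$rotation_range > 0) {
      pts <- do.call(rbind, lapply(landmarks, valid_points))
      theta <- 0
      for (attempt in seq_len(max(1L, config$max_attempts))) {
        cand <- runif(1, -config$rotation_range, config$rotation_range) * pi / 180
        if (!is.null(pts) && nrow(pts)) {
          q <- rotate_points(pts, cand, ctr)
          oob <- any(q[, 1L] < 0 | q[, 1L] > w - 1 | q[, 2L] < 0 | q[, 2L] > h - 1)
          if (oob) {
            if (config$oob_policy == "skip") break
            next
          }
        }
        theta <- cand
        break
      }
      if (theta != 0) {
        # inverse-map pixel grid (0-based coordinates)
        gx <- matrix(rep(0:(w - 1), each = h), h, w)
        gy <- matrix(rep(0:(h - 1), times = w), h, w)
        src <- rotate_points(cbind(as.numeric(gx), as.numeric(gy)), -theta, ctr)
        pixels <- warp_bilinear(pixels, matrix(src[, 1L], h, w),
                                matrix(src[, 2L], h, w))
        landmarks <- transform_landmarks(landmarks,
                                         function(p) rotate_points(p, theta, ctr))
      }
    }
    annotated_image(pixels, landmarks, img$image_id)
  })
}

#' Elastic deformation and pixel noise
#'
#' Applies a smooth random displacement field (Gaussian-filtered white
#' noise, rescaled to amplitude `elastic_alpha`, smoothness
#' `elastic_sigma`) identically to pixels and landmark coordinates, then
#' adds Gaussian pixel noise and re-clips intensities to `[0, 1]`. A
#' landmark moves by the field evaluated at its location; pixels are
#' backward-warped with the negated field so content moves the same way.
#'
#' @inheritParams random_caudal_crop
#' @export
elastic_and_noise <- function(img, config = augment_config(), seed = config$seed) {
  with_seed(seed, {
    pixels <- img$pixels
    landmarks <- img$landmarks
    h <- nrow(pixels); w <- ncol(pixels)
    if (config$elastic_alpha > 0) {
      smooth_field <- function() {
        f <- blur_image(matrix(rnorm(h * w), h, w), config$elastic_sigma)
        f / max(abs(f), 1e-12) * config$elastic_alpha
      }
      dx <- smooth_field(); dy <- smooth_field()
      gx <- matrix(rep(0:(w - 1), each = h), h, w)
      gy <- matrix(rep(0:(h - 1), times = w), h, w)
      pixels <- warp_bilinear(pixels, gx - dx, gy - dy)
      landmarks <- transform_landmarks(landmarks, function(p) {
        cbind(pmin(pmax(p[, 1L] + interp_field(dx, p), 0), w - 1),
              pmin(pmax(p[, 2L] + interp_field(dy, p), 0), h - 1))
      })
    }
    if (config$noise_sd > 0) {
      pixels <- pixels + rnorm(h * w, 0, config$noise_sd)
    }
    pixels <- pmin(pmax(pixels, 0), 1)
    annotated_image(pixels, landmarks, img$image_id)
  })
}

# Full training-time augmentation for whole-image networks (presence and
# global corners): caudal crop, then rotation/flip, then elastic + noise.
augment_full <- function(img, config, seed = NULL) {
  with_seed(seed, {
    img <- random_caudal_crop(img, config, seed = NULL)
    img <- random_rotate_flip(img, config, seed = NULL)
    elastic_and_noise(img, config, seed = NULL)
  })
}
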