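#' Configuration of the synthetic spine radiograph simulator
#'
#' The simulator renders sagittal-radiograph-like images of the thoracolumbar
#' spine with exact ground-truth corner landmarks, emulating the statistical
#' structure of a clinical lumbar-spine archive: variable fields of view
#' (most-cranial visible level between T9 and L1, most-caudal S1), variable
#' resolution, lordosis and sacral-slope distributions matching published
#' population statistics (L1-L5 mean 36.3 deg on support 0.1-86.8,
#' SS mean 35.8 deg on support 0-89.4, L1-S1 emerging around 49.9), plus
#' radiographic nuisances: noise, collimation black borders, brightness
#' extremes and optional instrumentation-like bright hardware.
#'
#' Angles are sampled from truncated normals on the published supports;
#' vertebra sizes shrink gradually toward the cranial end and are jittered
#' per image to emulate uncalibrated pixel spacing.
#'
#' @param image_height,image_width canvas size in pixels.
#' @param levels_range character pair `c(most_cranial, most_caudal)` bounding
#'   the simulated field of view (default `c("T9", "S1")`). The per-image
#'   most-cranial level is drawn between `levels_range[1]` and L1 with
#'   `cranial_weights`.
#' @param cranial_weights sampling weights for the per-image most-cranial
#'   level, cranial to caudal. The default reproduces the most-cranial-level
#'   frequencies implied by a published clinical level census (T9 rare, T11
#'   the mode, full-lumbar-only views uncommon).
#' @param lordosis_L1L5,sacral_slope length-4 vectors
#'   `c(mean, sd, min, max)` in degrees of the truncated-normal samplers.
#' @param lumbosacral_disc range (degrees) of the extra L5-S1 disc wedge
#'   added to L1-L5 to produce the L1-S1 angle.
#' @param vertebra_base_size nominal L5 body height in pixels; `NULL` means
#'   `image_height / 18` (so a full T9..S1 column fits the canvas).
#' @param size_gradient fractional shrink of body height per level going
#'   cranially.
#' @param size_jitter per-image uniform scale jitter (fraction).
#' @param noise_sd additive Gaussian intensity noise (unit intensity scale).
#' @param blur_sigma Gaussian blur applied to the rendered scene, pixels.
#' @param black_border_prob,brightness_extreme_prob,instrumentation_prob
#'   probabilities of the three artifact families.
#' @param seed master seed; `NULL` uses the current RNG stream.
#' @return validated config object of class `spine_sim_config`.
#' @export
spine_sim_config <- function(image_height = 256L, image_width = 256L,
                             levels_range = c("T9", "S1"),
                             cranial_weights = c(0.08, 0.26, 0.37, 0.25, 0.04),
                             lordosis_L1L5 = c(mean = 36.3, sd = 16, min = 0.1, max = 86.8),
                             sacral_slope = c(mean = 35.8, sd = 12, min = 0, max = 89.4),
                             lumbosacral_disc = c(7, 20),
                             vertebra_base_size = NULL,
                             size_gradient = 0.03,
                             size_jitter = 0.12,
                             noise_sd = 0.03,
                             blur_sigma = 0.8,
                             black_border_prob = 0.3,
                             brightness_extreme_prob = 0.1,
                             instrumentation_prob = 0.1,
                             seed = NULL) {
  stopifnot(image_height >= 48, image_width >= 48)
  level_ordinal(levels_range)
  if (level_ordinal(levels_range[1L]) >= level_ordinal(levels_range[2L])) {
    stop("levels_range must be (cranial, caudal)", call. = FALSE)
  }
  chk_rng <- function(r, lo, hi, what) {
    if (r[["min"]] >= r[["max"]] || r[["sd"]] <= 0 || r[["min"]] < lo || r[["max"]] > hi) {
      stop(what, " range degenerate or outside support [", lo, ", ", hi, "]",
           call. = FALSE)
    }
  }
  chk_rng(lordosis_L1L5, 0, 90, "lordosis_L1L5")
  chk_rng(sacral_slope, 0, 90, "sacral_slope")
  probs <- c(black_border_prob, brightness_extreme_prob, instrumentation_prob)
  if (any(probs < 0 | probs > 1)) stop("artifact probabilities must be in [0, 1]",
                                       call. = FALSE)
  if (is.null(vertebra_base_size)) vertebra_base_size <- image_height / 18
  if (vertebra_base_size <= 2) stop("vertebra_base_size too small", call. = FALSE)
  cranial_choices <- level_seq(levels_range[1L], "L1")
  if (length(cranial_weights) != length(cranial_choices)) {
    cranial_weights <- rep(1, length(cranial_choices))
  }
  structure(list(
    image_height = as.integer(image_height), image_width = as.integer(image_width),
    levels_range = levels_range, cranial_choices = cranial_choices,
    cranial_weights = cranial_weights / sum(cranial_weights),
    lordosis_L1L5 = lordosis_L1L5, sacral_slope = sacral_slope,
    lumbosacral_disc = lumbosacral_disc,
    vertebra_base_size = vertebra_base_size, size_gradient = size_gradient,
    size_jitter = size_jitter, noise_sd = noise_sd, blur_sigma = blur_sigma,
    black_border_prob = black_border_prob,
    brightness_extreme_prob = brightness_extreme_prob,
    instrumentation_prob = instrumentation_prob, seed = seed
  ), class = "spine_sim_config")
}

rtrunc_norm1 <- function(mean, sd, lo, hi) {
  p <- runif(1, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  min(max(qnorm(p, mean, sd), lo), hi)
}

deg <- pi / 180

# direction along an endplate with slope angle a (degrees): anterior = +x,
# positive a lifts the anterior end (y axis points down the image)
.u <- function(a) c(cos(a * deg), -sin(a * deg))
# cranial normal of an endplate (points up the image for |a| < 90)
.n <- function(a) c(-sin(a * deg), -cos(a * deg))

# Lay out the vertebral chain. Returns per-level corner sets in a local
# frame plus auxiliary quads for rendering.
build_spine_geometry <- function(cfg, params) {
  levels <- level_seq(params$most_cranial, "S1")
  nlev <- length(levels)
  s <- params$scale
  ords <- level_ordinal(levels)
  heights <- cfg$vertebra_base_size * (1 - cfg$size_gradient * (23 - ords)) * s
  widths <- 1.45 * heights * runif(nlev, 0.93, 1.07)

  # endplate slope angles, bottom-up. L1-S1 = L1L5 + lumbosacral disc wedge.
  a_s1 <- params$ss
  a_l1up <- a_s1 - params$l1s1
  a_l5low <- a_l1up + params$l1l5
  # distribute the lumbar rotation over 5 bodies + 4 discs (Dirichlet)
  wseg <- rgamma(9L, shape = 2); wseg <- wseg / sum(wseg)
  lumbar_steps <- -params$l1l5 * wseg
  # slopes per level: list lev -> c(lower, upper); S1 only upper
  slope <- list(S1 = c(NA, a_s1))
  a <- a_l5low
  li <- 1L
  for (lev in c("L5", "L4", "L3", "L2", "L1")) {
    up <- a + lumbar_steps[li]; li <- li + 1L
    slope[[lev]] <- c(a, up)
    a <- up + if (li <= 9L) lumbar_steps[li] else 0  # disc above
    li <- li + 1L
  }
  # thoracic levels: mild kyphotic reversal going up
  if (level_ordinal(params$most_cranial) <= level_ordinal("T12")) {
    a <- slope[["L1"]][2L] + runif(1, 0.5, 2.5)  # T12-L1 disc
    for (lev in rev(level_seq(params$most_cranial, "T12"))) {
      up <- a + runif(1, 1, 4)
      slope[[lev]] <- c(a, up)
      a <- up + runif(1, 0.5, 2.5)
    }
  }

  # walk the chain from the S1 endplate upward
  corners <- list()
  w_s1 <- widths[[match("L5", levels)]] * 1.05
  c_s1 <- c(0, 0)
  p_ua <- c_s1 + w_s1 / 2 * .u(a_s1)
  p_up <- c_s1 - w_s1 / 2 * .u(a_s1)
  corners[["S1"]] <- rbind(p_ua, p_up, c(NA, NA), c(NA, NA))
  # sacrum render quad: drops caudally and posteriorly from the endplate
  sac_drop <- heights[[nlev]] * 1.6
  sac <- rbind(p_ua, p_up,
               p_up - sac_drop * .n(a_s1) - c(0.45 * w_s1, 0),
               p_ua - sac_drop * .n(a_s1) - c(0.55 * w_s1, 0))
  body_quads <- list(sac)

  above <- rev(setdiff(levels, "S1"))  # L5 first, then up
  prev_up_center <- c_s1
  prev_up_slope <- a_s1
  for (lev in above) {
    k <- match(lev, levels)
    h <- heights[[k]]; w <- widths[[k]]
    sl <- slope[[lev]]
    d <- h * runif(1, 0.25, 0.4)  # disc height below this vertebra
    c_low <- prev_up_center + d * .n((prev_up_slope + sl[1L]) / 2)
    c_up <- c_low + h * .n((sl[1L] + sl[2L]) / 2)
    la <- c_low + w / 2 * .u(sl[1L]); lp <- c_low - w / 2 * .u(sl[1L])
    ua <- c_up + w / 2 * .u(sl[2L]); up <- c_up - w / 2 * .u(sl[2L])
    corners[[lev]] <- rbind(ua, up, la, lp)
    body_quads[[length(body_quads) + 1L]] <- rbind(ua, up, lp, la)
    prev_up_center <- c_up
    prev_up_slope <- sl[2L]
  }
  list(levels = levels, corners = corners, body_quads = body_quads,
       heights = stats::setNames(heights, levels),
       widths = stats::setNames(widths, levels))
}

fill_quad <- function(canvas, quad, value) {
  h <- nrow(canvas); w <- ncol(canvas)
  xr <- floor(min(quad[, 1L])):ceiling(max(quad[, 1L]))
  yr <- floor(min(quad[, 2L])):ceiling(max(quad[, 2L]))
  xr <- xr[xr >= 0 & xr <= w - 1L]; yr <- yr[yr >= 0 & yr <= h - 1L]
  if (!length(xr) || !length(yr)) return(canvas)
  px <- rep(xr, each = length(yr)); py <- rep(yr, times = length(xr))
  # orientation of the vertex cycle, then per-edge half-plane tests
  nxt <- c(2:4, 1)
  orient <- sign(sum(quad[, 1L] * quad[nxt, 2L] - quad[nxt, 1L] * quad[, 2L]))
  if (orient == 0) return(canvas)
  inside <- rep(TRUE, length(px))
  for (i in 1:4) {
    a <- quad[i, ]; b <- quad[nxt[i], ]
    cr <- (b[1L] - a[1L]) * (py - a[2L]) - (b[2L] - a[2L]) * (px - a[1L])
    inside <- inside & (orient * cr >= -1e-9)
  }
  canvas[cbind(py[inside] + 1L, px[inside] + 1L)] <- value
  canvas
}

draw_segment <- function(canvas, p1, p2, radius, value, mode = c("set", "max")) {
  mode <- match.arg(mode)
  h <- nrow(canvas); w <- ncol(canvas)
  xr <- floor(min(p1[1], p2[1]) - radius):ceiling(max(p1[1], p2[1]) + radius)
  yr <- floor(min(p1[2], p2[2]) - radius):ceiling(max(p1[2], p2[2]) + radius)
  xr <- xr[xr >= 0 & xr <= w - 1L]; yr <- yr[yr >= 0 & yr <= h - 1L]
  if (!length(xr) || !length(yr)) return(canvas)
  px <- rep(xr, each = length(yr)); py <- rep(yr, times = length(xr))
  v <- p2 - p1
  len2 <- sum(v^2)
  t <- if (len2 < 1e-12) rep(0, length(px)) else
    pmin(pmax(((px - p1[1]) * v[1] + (py - p1[2]) * v[2]) / len2, 0), 1)
  d2 <- (px - (p1[1] + t * v[1]))^2 + (py - (p1[2] + t * v[2]))^2
  sel <- d2 <= radius^2
  idx <- cbind(py[sel] + 1L, px[sel] + 1L)
  canvas[idx] <- if (mode == "max") pmax(canvas[idx], value) else value
  canvas
}

#' Simulate one annotated spine radiograph
#'
#' Renders the vertebral bodies as bright convex quadrilaterals along a
#' smooth sagittal curve whose endplate slopes realize the sampled L1-L5
#' lordosis and sacral slope exactly, stores the corner landmarks exactly
#' where rendered, and applies the configured radiographic artifacts.
#'
#' @param config a [spine_sim_config()].
#' @param seed integer seed for this image; defaults to `config$seed`.
#' @param image_id identifier stored on the image.
#' @return a `ground_truth_record`: list with `image` ([annotated_image()]),
#'   `true_angles` (recomputed from the stored corners), and
#'   `generator_params` (the sampled angles, levels and scale).
#' @export
simulate_image <- function(config, seed = config$seed, image_id = "sim") {
  with_seed(seed, {
    params <- list(
      most_cranial = sample(config$cranial_choices, 1L,
                            prob = config$cranial_weights),
      l1l5 = rtrunc_norm1(config$lordosis_L1L5[["mean"]], config$lordosis_L1L5[["sd"]],
                          config$lordosis_L1L5[["min"]], config$lordosis_L1L5[["max"]]),
      ss = rtrunc_norm1(config$sacral_slope[["mean"]], config$sacral_slope[["sd"]],
                        config$sacral_slope[["min"]], config$sacral_slope[["max"]]),
      scale = runif(1, 1 - config$size_jitter, 1 + config$size_jitter)
    )
    params$l1s1 <- min(params$l1l5 + runif(1, config$lumbosacral_disc[1L],
                                           config$lumbosacral_disc[2L]), 89)
    geo <- build_spine_geometry(config, params)

    # place the chain on the canvas
    all_pts <- do.call(rbind, c(geo$corners, geo$body_quads))
    all_pts <- all_pts[stats::complete.cases(all_pts), , drop = FALSE]
    margin <- 4 + 2 * config$blur_sigma
    span <- apply(all_pts, 2L, function(v) diff(range(v)))
    slack <- c(config$image_width, config$image_height) - span - 2 * margin
    if (any(slack < 0)) {
      stop(sprintf("layout error: %d levels (%s..S1) do not fit a %dx%d canvas",
                   length(geo$levels), params$most_cranial,
                   config$image_width, config$image_height), call. = FALSE)
    }
    shift <- -apply(all_pts, 2L, min) + margin + runif(2) * slack
    place <- function(m) sweep(m, 2L, shift, "+")

    # background with coarse mottle
    h <- config$image_height; w <- config$image_width
    canvas <- matrix(runif(1, 0.06, 0.16), h, w)
    canvas <- canvas + blur_image(matrix(rnorm(h * w, 0, 1), h, w), sigma = 6) * 0.6
    canvas <- pmin(pmax(canvas, 0), 0.35)

    # faint rib shadows anterior to the thoracic bodies: the visual cue that
    # separates thoracic from lumbar levels on a sagittal radiograph
    for (lev in geo$levels) {
      if (level_ordinal(lev) > level_ordinal("T12")) next
      q <- place(geo$corners[[lev]])
      ctr <- colMeans(q)
      w_lev <- geo$widths[[lev]]; h_lev <- geo$heights[[lev]]
      p0 <- ctr + c(0.30 * w_lev, 0.10 * h_lev)
      p1 <- p0 + c(0.90 * w_lev, 0.40 * h_lev)
      p2 <- p1 + c(0.80 * w_lev, 0.65 * h_lev)
      rv <- runif(1, 0.36, 0.48)
      canvas <- draw_segment(canvas, p0, p1, h_lev / 4.5, rv, mode = "max")
      canvas <- draw_segment(canvas, p1, p2, h_lev / 5.5, rv, mode = "max")
    }

    for (q in geo$body_quads) {
      canvas <- fill_quad(canvas, place(q), runif(1, 0.55, 0.8))
    }

    instrumented <- runif(1) < config$instrumentation_prob
    if (instrumented) {
      lumb <- intersect(c("L2", "L3", "L4", "L5"), geo$levels)
      if (length(lumb) >= 2L) {
        ends <- c(lumb[1L], lumb[length(lumb)])
        post <- function(lev) {
          m <- colMeans(place(geo$corners[[lev]])[c(2, 4), , drop = FALSE])
          m - c(0.55 * geo$widths[[lev]], 0)
        }
        rad <- max(1.2, geo$heights[[ends[2L]]] / 9)
        canvas <- draw_segment(canvas, post(ends[1L]), post(ends[2L]), rad, 0.95)
        for (lev in ends) {  # pedicle-screw-like strokes into the bodies
          b <- colMeans(place(geo$corners[[lev]])[stats::complete.cases(geo$corners[[lev]]), ,
                                                  drop = FALSE])
          canvas <- draw_segment(canvas, post(lev), b, rad * 0.8, 0.95)
        }
      }
    }

    canvas <- blur_image(canvas, config$blur_sigma)
    if (config$noise_sd > 0) canvas <- canvas + rnorm(h * w, 0, config$noise_sd)

    bright <- runif(1) < config$brightness_extreme_prob
    if (bright) {
      canvas <- if (runif(1) < 0.5) canvas * runif(1, 0.4, 0.6)
                else canvas + runif(1, 0.2, 0.35)
    }
    canvas <- pmin(pmax(canvas, 0), 1)

    # collimation borders, kept clear of the spine
    landmarks_pts <- place(do.call(rbind, geo$corners))
    landmarks_pts <- landmarks_pts[stats::complete.cases(landmarks_pts), , drop = FALSE]
    bordered <- runif(1) < config$black_border_prob
    if (bordered) {
      gap <- 3
      lims <- c(left = min(landmarks_pts[, 1L]) - gap,
                right = w - 1 - max(landmarks_pts[, 1L]) - gap,
                top = min(landmarks_pts[, 2L]) - gap,
                bottom = h - 1 - max(landmarks_pts[, 2L]) - gap)
      for (side in sample(names(lims), sample(1:2, 1L))) {
        bw <- floor(runif(1, 0, max(0, min(lims[[side]], 0.2 * min(h, w)))))
        if (bw < 2) next
        switch(side,
               left = canvas[, 1:bw] <- 0,
               right = canvas[, (w - bw + 1):w] <- 0,
               top = canvas[1:bw, ] <- 0,
               bottom = canvas[(h - bw + 1):h, ] <- 0)
      }
    }

    landmarks <- lapply(geo$corners, function(m) {
      pm <- matrix(NA_real_, 4L, 2L)
      ok <- stats::complete.cases(m)
      pm[ok, ] <- place(m[ok, , drop = FALSE])
      corner_set(pm, valid = ok)
    })

    img <- annotated_image(canvas, landmarks, image_id)
    structure(list(
      image = img,
      true_angles = angles_from_corners(img$landmarks),
      generator_params = c(params, list(levels = geo$levels,
                                        instrumented = instrumented))
    ), class = "ground_truth_record")
  })
}

#' @export
print.ground_truth_record <- function(x, ...) {
  cat(sprintf("<ground_truth_record> %s (%s..S1)\n", x$image$image_id,
              x$generator_params$most_cranial))
  print(x$true_angles)
  invisible(x)
}

#' Simulate a dataset with train/validation/test splits
#'
#' Draws `n_images` independent radiographs (per-image seeds derived
#' deterministically from the master seed), splits them disjointly by
#' `split_fractions`, and optionally writes PNG images, per-split annotation
#' CSVs and a manifest YAML to `out_dir`.
#'
#' @param config a [spine_sim_config()].
#' @param n_images number of images (>= 3).
#' @param split_fractions three fractions summing to 1.
#' @param out_dir output directory, or `NULL` to keep everything in memory.
#' @return named list `train`, `validation`, `test` of `ground_truth_record`s.
#' @export
simulate_dataset <- function(config, n_images,
                             split_fractions = c(0.8, 0.1, 0.1),
                             out_dir = NULL) {
  if (n_images < 3) stop("split error: need at least 3 images", call. = FALSE)
  if (length(split_fractions) != 3L || abs(sum(split_fractions) - 1) > 1e-9) {
    stop("split error: fractions must be 3 values summing to 1", call. = FALSE)
  }
  master <- if (is.null(config$seed)) sample.int(2147483646L, 1L) else config$seed
  ids <- sprintf("sim_%05d", seq_len(n_images))
  records <- lapply(seq_len(n_images), function(i) {
    simulate_image(config, seed = derive_seed(master, i), image_id = ids[[i]])
  })
  bounds <- round(cumsum(split_fractions) * n_images)
  counts <- diff(c(0L, bounds))
  membership <- rep(c("train", "validation", "test"), counts)
  out <- split(records, factor(membership, levels = c("train", "validation", "test")))

  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
    for (r in records) {
      write_image(r$image$pixels,
                  file.path(out_dir, "images", paste0(r$image$image_id, ".png")))
    }
    for (s in names(out)) {
      write_annotations(landmark_map(lapply(out[[s]], `[[`, "image")),
                        file.path(out_dir, paste0("annotations_", s, ".csv")))
    }
    yaml::write_yaml(list(master_seed = master, n_images = n_images,
                          split_counts = as.list(stats::setNames(as.integer(counts),
                                                                 names(out))),
                          config = config[setdiff(names(config), "cranial_choices")]),
                     file.path(out_dir, "manifest.yaml"))
  }
  out
}
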