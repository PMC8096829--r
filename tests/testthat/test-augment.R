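sim_annotated <- function(seed = 5, ...) {
  simulate_image(tiny_sim_config(seed = seed, ...), seed = seed)$image
}

test_that("caudal crops cut between vertebrae and respect the constraints", {
  cfg <- augment_config(caudal_crop_prob = 1, seed = NULL)
  removed_any <- FALSE
  for (simseed in 1:6) {
    img <- sim_annotated(simseed, cranial_weights = c(0, 0, 1, 0, 0))  # T11..S1
    for (s in 1:8) {
      out <- random_caudal_crop(img, cfg, seed = s)
      kept <- names(out$landmarks)
      expect_gte(length(kept), cfg$min_visible)
      caudal <- kept[which.max(level_ordinal(kept))]
      if (length(kept) < length(img$landmarks)) {
        removed_any <- TRUE
        expect_true(caudal %in% c("L3", "L4", "L5"))
        expect_lt(nrow(out$pixels), nrow(img$pixels))
        # all remaining landmarks are above the cut
        top <- nrow(out$pixels)
        for (cs in out$landmarks) expect_true(all(valid_points(cs)[, 2] < top))
      } else {
        expect_identical(caudal, "S1")  # no-op keeps the full column
      }
    }
  }
  expect_true(removed_any)
  # determinism under a fixed seed
  img <- sim_annotated(3, cranial_weights = c(0, 0, 1, 0, 0))
  expect_identical(random_caudal_crop(img, cfg, seed = 4),
                   random_caudal_crop(img, cfg, seed = 4))
})

test_that("a three-vertebra image is never cropped below min_visible", {
  lm <- list(L3 = rect_corners(40, 20, 30, 18),
             L4 = rect_corners(40, 50, 30, 18),
             L5 = rect_corners(40, 80, 30, 18))
  img <- annotated_image(matrix(0.5, 120, 110), lm, "three")
  cfg <- augment_config(caudal_crop_prob = 1)
  for (s in 1:8) {
    out <- random_caudal_crop(img, cfg, seed = s)
    expect_gte(length(out$landmarks), 3L)
  }
  expect_error(random_caudal_crop(annotated_image(matrix(0.5, 50, 50),
                                                  lm["L5"], "one"), cfg),
               "min_visible")
})

test_that("zero-amplitude transforms are exact identities", {
  img <- sim_annotated(7)
  cfg0 <- augment_config(rotation_range = 0, flip_prob = 0,
                         elastic_alpha = 0, noise_sd = 0,
                         caudal_crop_prob = 0)
  out <- random_rotate_flip(img, cfg0, seed = 1)
  expect_identical(out$pixels, img$pixels)
  expect_identical(out$landmarks, img$landmarks)
  out2 <- elastic_and_noise(img, cfg0, seed = 1)
  expect_equal(out2$pixels, img$pixels)
  expect_identical(out2$landmarks, img$landmarks)
})

test_that("rotation follows the published point convention", {
  # 90 degrees about the center of a 100x100 canvas sends (10, 0) to (99, 10)
  p <- spinemark:::rotate_points(c(10, 0), pi / 2, c(49.5, 49.5))
  expect_equal(p, cbind(99, 10))
})

test_that("horizontal flips swap anterior and posterior corner roles", {
  img <- sim_annotated(9)
  cfg <- augment_config(rotation_range = 0, flip_prob = 1)
  out <- random_rotate_flip(img, cfg, seed = 2)
  w <- ncol(img$pixels)
  for (lev in names(img$landmarks)) {
    a <- img$landmarks[[lev]]; b <- out$landmarks[[lev]]
    expect_identical(a$valid, b$valid)
    # the flipped UA is the mirrored original UP, and vice versa
    expect_equal(b$points["UA", ], c(x = (w - 1) - a$points["UP", "x"],
                                     y = a$points["UP", "y"]))
    expect_equal(b$points["LP", ], c(x = (w - 1) - a$points["LA", "x"],
                                     y = a$points["LA", "y"]))
  }
  # flipping twice restores landmarks including corner roles
  back <- random_rotate_flip(out, cfg, seed = 3)
  for (lev in names(img$landmarks)) {
    expect_equal(back$landmarks[[lev]]$points, img$landmarks[[lev]]$points)
  }
  expect_equal(back$pixels, img$pixels)
})

test_that("rotated landmarks stay glued to the rotated anatomy", {
  img <- sim_annotated(11, noise_sd = 0, black_border_prob = 0,
                       brightness_extreme_prob = 0, instrumentation_prob = 0)
  cfg <- augment_config(rotation_range = 10, flip_prob = 0)
  out <- random_rotate_flip(img, cfg, seed = 6)
  bg <- median(out$pixels)
  for (cs in out$landmarks) {
    for (ci in which(cs$valid)) {
      p <- round(cs$points[ci, ])
      nb <- out$pixels[pmax(1, p[2]):pmin(nrow(out$pixels), p[2] + 2),
                       pmax(1, p[1]):pmin(ncol(out$pixels), p[1] + 2)]
      expect_gt(max(nb), bg + 0.08)
    }
  }
})

test_that("elastic deformation moves pixels and landmarks together", {
  img <- sim_annotated(13)
  cfg <- augment_config(elastic_alpha = 3, elastic_sigma = 10, noise_sd = 0)
  out <- elastic_and_noise(img, cfg, seed = 8)
  # landmark displacement is bounded by the field amplitude
  for (lev in names(img$landmarks)) {
    d <- valid_points(out$landmarks[[lev]]) - valid_points(img$landmarks[[lev]])
    expect_lte(max(abs(d)), cfg$elastic_alpha + 1e-9)
  }
  # a bright marker painted at a landmark travels with it: the deformation
  # field is a pure function of the seed, so re-running it on a marker
  # image shows where that location went
  lm <- valid_points(img$landmarks[[1L]])[1L, ]
  marker <- img$pixels * 0
  marker[round(lm[2]) + 1, round(lm[1]) + 1] <- 1
  mimg <- annotated_image(marker, img$landmarks[1L], "marker")
  mout <- elastic_and_noise(mimg, cfg, seed = 8)
  peak <- which(mout$pixels == max(mout$pixels), arr.ind = TRUE)[1L, ]
  moved <- valid_points(mout$landmarks[[1L]])[1L, ]
  expect_lt(sqrt(sum((c(peak[2] - 1, peak[1] - 1) - moved)^2)), 2)
  # noise-only calls leave landmarks bit-identical
  cfgn <- augment_config(elastic_alpha = 0, noise_sd = 0.05)
  outn <- elastic_and_noise(img, cfgn, seed = 9)
  expect_identical(outn$landmarks, img$landmarks)
  expect_false(identical(outn$pixels, img$pixels))
  expect_true(all(outn$pixels >= 0 & outn$pixels <= 1))
})

test_that("intensity normalization handles bit depths and degenerate input", {
  m8 <- matrix(c(0, 255, 128, 64), 2, 2)
  expect_equal(normalize_intensity(m8)[1:2], c(0, 1))
  expect_equal(normalize_intensity(matrix(c(0, 65535), 1, 2))[2], 1)
  unit <- matrix(c(0.2, 0.8), 1, 2)
  expect_identical(normalize_intensity(unit), unit)
  expect_equal(max(normalize_intensity(m8, mode = "minmax")), 1)
  expect_warning(z <- normalize_intensity(matrix(5, 2, 2), mode = "minmax"),
                 "constant")
  expect_equal(z, matrix(0, 2, 2))
})
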