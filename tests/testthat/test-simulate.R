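test_that("simulator configs validate their ranges and probabilities", {
  expect_s3_class(tiny_sim_config(), "spine_sim_config")
  expect_error(spine_sim_config(black_border_prob = 1.5), "probabilities")
  expect_error(spine_sim_config(lordosis_L1L5 = c(mean = 30, sd = 10,
                                                  min = 50, max = 40)),
               "degenerate")
  expect_error(spine_sim_config(sacral_slope = c(mean = 30, sd = 10,
                                                 min = 0, max = 95)),
               "support")
  expect_error(spine_sim_config(levels_range = c("S1", "T9")), "cranial")
})

test_that("the same seed reproduces a simulated image bit for bit", {
  cfg <- tiny_sim_config(seed = 33)
  a <- simulate_image(cfg, seed = 9)
  b <- simulate_image(cfg, seed = 9)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$image$landmarks, b$image$landmarks)
  expect_identical(a$generator_params, b$generator_params)
  expect_false(identical(a$image$pixels, simulate_image(cfg, seed = 10)$image$pixels))
})

test_that("a forced T9 field of view renders exactly ten levels", {
  cfg <- tiny_sim_config(seed = 1, cranial_weights = c(1, 0, 0, 0, 0))
  r <- simulate_image(cfg, seed = 3)
  expect_identical(names(r$image$landmarks), level_seq("T9", "S1"))
  expect_length(r$image$landmarks, 10L)
  # S1 carries its upper endplate only
  expect_identical(r$image$landmarks$S1$valid, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("stored corners land on rendered vertebra structure", {
  cfg <- tiny_sim_config(seed = 8, noise_sd = 0, black_border_prob = 0,
                         brightness_extreme_prob = 0, instrumentation_prob = 0)
  for (s in 1:5) {
    r <- simulate_image(cfg, seed = s)
    px <- r$image$pixels
    bg <- median(px)  # most of the canvas is background
    for (cs in r$image$landmarks) {
      for (ci in which(cs$valid)) {
        p <- round(cs$points[ci, ])
        # the corner sits on the blurred body boundary: the brightest pixel
        # in its immediate neighborhood belongs to the rendered vertebra
        nb <- px[pmax(1, p[2]):pmin(nrow(px), p[2] + 2),
                 pmax(1, p[1]):pmin(ncol(px), p[1] + 2)]
        expect_gt(max(nb), bg + 0.1)
      }
    }
  }
})

test_that("recomputed angles match the generator's sampled targets", {
  cfg <- tiny_sim_config(seed = 21)
  for (s in 1:20) {
    r <- simulate_image(cfg, seed = s)
    a <- angles_from_corners(r$image$landmarks)
    expect_lt(abs(a$L1_L5 - r$generator_params$l1l5), 0.5)
    expect_lt(abs(a$SS - r$generator_params$ss), 0.5)
    expect_lt(abs(a$L1_S1 - r$generator_params$l1s1), 0.5)
  }
})

test_that("sampled angle statistics respect the configured population", {
  cfg <- tiny_sim_config(seed = 77)
  angs <- vapply(1:300, function(i) {
    g <- simulate_image(cfg, seed = i)$generator_params
    c(g$l1l5, g$ss)
  }, numeric(2))
  expect_lt(abs(mean(angs[1, ]) - 36.3), 3)
  expect_lt(abs(mean(angs[2, ]) - 35.8), 3)
  expect_gte(min(angs[1, ]), 0.1); expect_lte(max(angs[1, ]), 86.8)
  expect_gte(min(angs[2, ]), 0); expect_lte(max(angs[2, ]), 89.4)
})

test_that("dataset simulation splits, writes and round-trips", {
  expect_error(simulate_dataset(tiny_sim_config(), 2), "at least 3")
  expect_error(simulate_dataset(tiny_sim_config(), 10, c(0.5, 0.2, 0.2)),
               "summing to 1")
  out <- withr::local_tempdir()
  cfg <- tiny_sim_config(seed = 4)
  sets <- simulate_dataset(cfg, 10, c(0.8, 0.1, 0.1), out_dir = out)
  expect_identical(lengths(sets), c(train = 8L, validation = 1L, test = 1L))
  ids <- unlist(lapply(sets, function(s) vapply(s, function(r) r$image$image_id,
                                                character(1))))
  expect_identical(anyDuplicated(ids), 0L)
  expect_length(list.files(file.path(out, "images"), pattern = "\\.png$"), 10L)
  man <- yaml::read_yaml(file.path(out, "manifest.yaml"))
  expect_equal(man$master_seed, 4)
  ann <- read_annotations(file.path(out, "annotations_train.csv"))
  expect_length(ann, 8L)
  img1 <- sets$train[[1L]]$image
  expect_equal(valid_points(ann[[img1$image_id]]$S1),
               valid_points(img1$landmarks$S1), tolerance = 1e-3)
  # PNG round trip preserves the rendered intensities to 8-bit precision
  px <- read_image(file.path(out, "images", paste0(img1$image_id, ".png")))
  expect_lt(max(abs(px - img1$pixels)), 1 / 255)
})

test_that("a canvas too small for the requested levels is a layout error", {
  cfg <- spine_sim_config(image_height = 64, image_width = 64,
                          vertebra_base_size = 12,
                          cranial_weights = c(1, 0, 0, 0, 0), seed = 1)
  expect_error(simulate_image(cfg, seed = 2), "layout error")
})
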