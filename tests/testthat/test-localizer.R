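test_that("backbone configs enforce the family/input-size contract", {
  expect_s3_class(backbone_config(input_size = 64), "backbone_config")
  expect_error(backbone_config(input_size = 200), "48..128")
  expect_error(backbone_config("standard-residual-50", input_size = 64),
               "512 or 1024")
  cfg <- backbone_config("standard-inception-v3", input_size = 512)
  expect_error(spinemark:::build_network(cfg, "heatmap"), "tiny-conv")
})

test_that("forward passes honor the published output-shape contracts", {
  set.seed(3)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  # presence: a 24-element vector, one sigmoid logit per level
  pn <- spinemark:::build_network(backbone_config(input_size = 64), "presence")
  expect_length(spinemark:::net_forward(pn, x)$out, 24L)
  # global localizer: 24 x 4 x 2 block of normalized coordinates
  gn <- spinemark:::build_network(
    backbone_config(input_size = 64, heatmap_channels = 96L), "heatmap")
  hm <- spinemark:::net_forward(gn, x)$out
  expect_identical(dim(hm)[3], 96L)
  coords <- spinemark:::dsnt_forward(hm)$coords
  expect_identical(dim(array(coords, c(4, 24, 2))), c(4L, 24L, 2L))
  expect_identical(dim(coords), c(96L, 2L))
  expect_true(all(coords >= -1 & coords <= 1))
  # refiner: 1 x 4 x 2
  rn <- spinemark:::build_network(
    backbone_config(input_size = 64, heatmap_channels = 4L), "heatmap")
  rc <- spinemark:::dsnt_forward(spinemark:::net_forward(rn, x)$out)$coords
  expect_identical(dim(rc), c(4L, 2L))
})

test_that("step-I targets are the resize-mapped, normalized truth corners", {
  img <- simulate_image(tiny_sim_config(seed = 19), seed = 2)$image
  bb <- backbone_config(input_size = 64)
  sm <- spinemark:::prepare_step1(img, bb)
  expect_identical(dim(sm$target), c(96L, 2L))
  expect_length(sm$mask, 96L)
  lev <- names(img$landmarks)[[1L]]
  rows <- level_ordinal(lev) * 4L + 1:4
  expect_true(all(sm$mask[rows[img$landmarks[[lev]]$valid]]))
  # manual mapping of the first corner
  p <- img$landmarks[[lev]]$points[1L, ]
  scale <- 64 / image_size(img)
  expect_equal(sm$target[rows[1L], ],
               as.numeric(normalize_coords(rbind(p * scale), c(64, 64))))
  # S1 lower corners masked out
  s1rows <- level_ordinal("S1") * 4L + 3:4
  expect_false(any(sm$mask[s1rows]))
  # presence target agrees with the landmark map
  expect_equal(sum(sm$presence), length(img$landmarks))
})

test_that("refiner crops map truth corners through the crop transform", {
  img <- simulate_image(tiny_sim_config(seed = 23), seed = 4)$image
  lev <- "L3"
  rc <- spinemark:::refiner_crop(img, lev, 64L, extension = 0.7, jitter = 0)
  tf <- rc$transform
  cs <- img$landmarks[[lev]]
  expected <- cbind((cs$points[, 1] - tf$offset[1]) * tf$scale[1],
                    (cs$points[, 2] - tf$offset[2]) * tf$scale[2])
  expect_equal(unname(valid_points(rc$image$landmarks[[lev]])),
               unname(expected), tolerance = 1e-9)
  tg <- spinemark:::refiner_targets(rc$image, 64L)
  expect_identical(dim(tg$target), c(4L, 2L))
  expect_true(all(tg$target[tg$mask, ] >= -1 & tg$target[tg$mask, ] <= 1))
  # round trip back to the original frame
  expect_equal(unname(to_original(expected, tf)), unname(cs$points),
               tolerance = 1e-9)
})

test_that("the default schedules carry the published hyperparameters", {
  expect_equal(formals(train_presence)$schedule,
               quote(train_schedule(learning_rate = 1e-4, batch_size = 16L)))
  expect_equal(formals(train_corners_global)$schedule,
               quote(train_schedule(learning_rate = 1e-3, batch_size = 8L)))
  expect_equal(formals(train_refiner)$schedule,
               quote(train_schedule(learning_rate = 1e-4, batch_size = 16L)))
  sch <- train_schedule()
  expect_identical(sch$max_epochs, 200L)
  expect_equal(sch$plateau_factor, 0.1)
  expect_identical(sch$plateau_patience, 10L)
})

# Memorization fixtures: tiny networks overfit to a handful of simulated
# images, shared by the oracle assertions and the inference-contract tests.
mem_cfg <- tiny_sim_config(seed = 41)
train_recs <- lapply(1:4, function(i) simulate_image(mem_cfg, seed = i,
                                                     image_id = paste0("m", i)))
mem_sch <- function(n) train_schedule(learning_rate = 3e-3, batch_size = 2L,
                                      max_epochs = n, plateau_patience = 10L)

test_that("each network memorizes a handful of images", {
  recs <- train_recs
  bb <- backbone_config(input_size = 64)
  pk <- train_presence(recs, recs, backbone = bb, schedule = mem_sch(50L), seed = 1)
  expect_lt(min(pk$history$train_loss), 0.05)
  expect_true(all(is.finite(pk$history$val_loss)))

  gk <- train_corners_global(recs, list(),
                             backbone = backbone_config(input_size = 64,
                                                        heatmap_channels = 96L),
                             schedule = mem_sch(60L), seed = 1)
  # mean normalized corner error on the training set
  err <- vapply(recs, function(r) {
    sm <- spinemark:::prepare_step1(r$image, gk$backbone)
    hd <- spinemark:::dsnt_forward(spinemark:::net_forward(gk$net, sm$x)$out)
    coord_loss(hd$coords, sm$target, sm$mask)
  }, numeric(1))
  expect_lt(mean(err), 0.05)

  rk <- train_refiner(recs[1:2], list(),
                      backbone = backbone_config(input_size = 64,
                                                 heatmap_channels = 4L),
                      schedule = mem_sch(60L), jitter = 0, seed = 1)
  pix_err <- c()
  for (r in recs[1:2]) {
    for (lev in names(r$image$landmarks)) {
      rc <- spinemark:::refiner_crop(r$image, lev, 64L, 0.7, 0)
      tg <- spinemark:::refiner_targets(rc$image, 64L)
      x <- spinemark:::make_input(rc$image$pixels, TRUE)
      co <- spinemark:::dsnt_forward(spinemark:::net_forward(rk$net, x)$out)$coords
      # error in original-image pixels
      po <- to_original(denormalize(co, c(64, 64)), rc$transform)
      pt <- to_original(denormalize(tg$target, c(64, 64)), rc$transform)
      d <- sqrt(rowSums((po - pt)^2))[tg$mask]
      pix_err <- c(pix_err, d)
    }
  }
  expect_lt(median(pix_err), 2)

  ckpts <<- list(presence = pk, global = gk, refiner = rk)
})

test_that("inference emits well-formed detections with audit transforms", {
  img <- train_recs[[1L]]$image
  det <- infer(img$pixels, ckpts$presence, ckpts$global, ckpts$refiner,
               threshold = 0.5)
  expect_gt(length(det), 0L)
  for (d in det) {
    expect_true(d$level %in% spine_levels())
    expect_true(d$presence_prob >= 0.5)
    expect_s3_class(d$corners, "corner_set")
    expect_s3_class(d$corners_step1, "corner_set")
    nv <- if (d$level == "S1") 2L else 4L
    expect_identical(sum(d$corners$valid), nv)
    expect_true(d$provenance %in% c("refined", "step-I-only"))
    if (d$provenance == "refined") {
      expect_s3_class(d$crop_transform, "crop_transform")
      # the audited crop really contains the step-I box center
      ctr <- colMeans(valid_points(d$corners_step1))
      inside <- to_cropped(rbind(ctr), d$crop_transform)
      expect_true(all(inside >= -d$crop_transform$output_size &
                        inside <= 2 * d$crop_transform$output_size))
    }
  }
  # a threshold no probability can reach yields a clean empty result
  expect_identical(infer(img$pixels, ckpts$presence, ckpts$global,
                         ckpts$refiner, threshold = 1.01), list())
  lmap <- detections_to_landmarks(det)
  expect_identical(names(lmap), vapply(det, `[[`, character(1), "level"))
})
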