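# Convenience layer tying the three networks together: train the full
# two-step pipeline on a simulated (or real, annotated) dataset and evaluate
# both stages on held-out images. This is what the worked examples, the
# test-scale experiments and the acceptance script drive.

#' Train the complete two-step pipeline
#'
#' Trains the presence classifier, the global corner localizer and the
#' single-vertebra refiner on the same training/validation sets. Defaults
#' are the package's test-scale recipe: tiny-conv backbones (128 px whole
#' image, 64 px crops) trained for a handful of epochs on a few hundred
#' simulated radiographs — enough to exercise every contract of the
#' pipeline on one CPU.
#'
#' @param train,val lists of `ground_truth_record` or [annotated_image()].
#' @param input_size whole-image input side for presence + global nets.
#' @param crop_size refiner input side.
#' @param epochs named vector with elements `presence`, `global`, `refiner`.
#' @param augment optional [augment_config()] for the whole-image nets.
#' @param seed master seed (weights, shuffling, jitter).
#' @param verbose print per-epoch losses.
#' @return list of three checkpoints: `presence`, `global`, `refiner`.
#' @export
fit_two_step <- function(train, val = list(), input_size = 128L,
                         crop_size = 64L,
                         epochs = c(presence = 10L, global = 10L, refiner = 6L),
                         augment = NULL, seed = 1L, verbose = FALSE) {
  presence <- train_presence(
    train, val,
    backbone = backbone_config(input_size = input_size),
    schedule = train_schedule(learning_rate = 3e-3, batch_size = 16L,
                              max_epochs = epochs[["presence"]],
                              plateau_patience = 4L),
    augment = augment, seed = derive_seed(seed, 1L), verbose = verbose)
  global <- train_corners_global(
    train, val,
    backbone = backbone_config(input_size = input_size, heatmap_channels = 96L),
    schedule = train_schedule(learning_rate = 3e-3, batch_size = 8L,
                              max_epochs = epochs[["global"]],
                              plateau_patience = 4L),
    augment = augment, warm_start = presence,
    seed = derive_seed(seed, 2L), verbose = verbose)
  refiner <- train_refiner(
    train, val,
    backbone = backbone_config(input_size = crop_size, heatmap_channels = 4L),
    schedule = train_schedule(learning_rate = 3e-3, batch_size = 16L,
                              max_epochs = epochs[["refiner"]],
                              plateau_patience = 4L),
    warm_start = global, seed = derive_seed(seed, 3L), verbose = verbose)
  list(presence = presence, global = global, refiner = refiner)
}

#' Evaluate the two-step pipeline on annotated images
#'
#' Runs [infer()] on each image and scores both stages against the ground
#' truth: the step-I (global) corners and the step-II (refined) corners,
#' each with the full evaluation suite, plus angle agreement computed from
#' the refined corners.
#'
#' @param fit list of checkpoints from [fit_two_step()].
#' @param test list of `ground_truth_record` or [annotated_image()].
#' @param threshold presence threshold passed to [infer()].
#' @return list with `step1` and `step2` ([evaluate_landmarks()] reports)
#'   and `detections` (per-image lists).
#' @export
evaluate_two_step <- function(fit, test, threshold = 0.5) {
  imgs <- as_images(test)
  truth <- landmark_map(imgs)
  truth_angles <- lapply(imgs, function(im) angles_from_corners(im$landmarks))
  pred1 <- list(); pred2 <- list(); pred_angles <- list()
  detections <- list()
  for (im in imgs) {
    det <- infer(im$pixels, fit$presence, fit$global, fit$refiner,
                 threshold = threshold)
    detections[[im$image_id]] <- det
    pred2[[im$image_id]] <- detections_to_landmarks(det)
    pred1[[im$image_id]] <- stats::setNames(
      lapply(det, `[[`, "corners_step1"),
      vapply(det, `[[`, character(1), "level"))
    pred_angles[[im$image_id]] <- angles_from_corners(pred2[[im$image_id]])
  }
  list(step1 = evaluate_landmarks(pred1, truth),
       step2 = evaluate_landmarks(pred2, truth,
                                  pred_angles = pred_angles,
                                  truth_angles = truth_angles),
       detections = detections)
}
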