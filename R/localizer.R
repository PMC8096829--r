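#' Backbone configuration for the three pipeline networks
#'
#' The published full-scale pipeline uses a ResNet-50 for vertebra presence
#' and Inception-V3 fully-convolutional trunks for the two corner
#' localizers, all pretrained and partially frozen. Those families are
#' declarable here for completeness, but the trainable family in this
#' package is `"tiny-conv"`: a strided convolution stack (~10^5 parameters,
#' optional coordinate channels) sized so that the whole pipeline trains in
#' minutes on one CPU. Presence nets end in a 24-way sigmoid head; corner
#' nets end in heatmap channels consumed by a DSNT head.
#'
#' @param family `"tiny-conv"`, `"standard-residual-50"` or
#'   `"standard-inception-v3"`.
#' @param input_size square input side in pixels. Standard families require
#'   1024 (whole image) or 512 (crops); tiny accepts 48-128.
#' @param heatmap_channels number of corner heatmap channels (96 for the
#'   24-vertebra global localizer, 4 for the single-vertebra refiner).
#' @param widths channel widths of the tiny trunk.
#' @param coord_channels append normalized x/y coordinate channels to the
#'   input (helps the position-dependent presence task).
#' @param pretrained,freeze_until transfer-learning knobs of the standard
#'   families; `freeze_until` (an integer count of leading frozen conv
#'   layers) is also honored by the tiny family.
#' @export
backbone_config <- function(family = c("tiny-conv", "standard-residual-50",
                                       "standard-inception-v3"),
                            input_size = 64L,
                            heatmap_channels = 4L,
                            widths = c(16L, 32L, 64L),
                            coord_channels = TRUE,
                            pretrained = FALSE,
                            freeze_until = NULL) {
  family <- match.arg(family)
  input_size <- as.integer(input_size)
  if (family == "tiny-conv") {
    if (input_size < 48L || input_size > 128L) {
      stop("tiny-conv supports input_size in 48..128", call. = FALSE)
    }
  } else if (!input_size %in% c(512L, 1024L)) {
    stop("standard families require input_size 512 or 1024", call. = FALSE)
  }
  structure(list(family = family, input_size = input_size,
                 heatmap_channels = as.integer(heatmap_channels),
                 widths = as.integer(widths),
                 coord_channels = isTRUE(coord_channels),
                 pretrained = isTRUE(pretrained), freeze_until = freeze_until),
            class = "backbone_config")
}

build_network <- function(config, head = c("heatmap", "presence")) {
  head <- match.arg(head)
  if (config$family != "tiny-conv") {
    stop("only the tiny-conv family is trainable in this package; ",
         "standard pretrained backbones are configuration-only", call. = FALSE)
  }
  w <- config$widths
  in_ch <- 1L + if (config$coord_channels) 2L else 0L
  layers <- list(
    layer_conv(in_ch, w[1L], 5L, stride = 2L),
    layer_relu(),
    layer_conv(w[1L], w[2L], 3L, stride = 2L),
    layer_relu(),
    layer_conv(w[2L], w[3L], 3L, stride = 1L),
    layer_relu()
  )
  if (head == "heatmap") {
    # one more stride-2 stage before the heatmaps: level identity needs a
    # receptive field spanning a good part of the column, and the DSNT
    # expectation keeps sub-cell precision on the coarser grid
    layers <- c(layers, list(
      layer_conv(w[3L], w[3L], 3L, stride = 2L),
      layer_relu(),
      layer_conv(w[3L], w[3L], 3L, stride = 1L),
      layer_relu(),
      layer_conv(w[3L], config$heatmap_channels, 3L)
    ))
  } else {
    # global-average-pool head: channel sums are translation-invariant, so
    # a channel that fires once per rib-bearing (or any) vertebra turns into
    # a count feature — exactly the evidence that decides which contiguous
    # run of levels is visible, wherever the spine sits in the canvas
    layers <- c(layers, list(
      layer_conv(w[3L], w[3L], 3L, stride = 1L),
      layer_relu(),
      layer_gap(),
      layer_dense(w[3L], 96L),
      layer_relu(),
      layer_dense(96L, 24L)
    ))
  }
  list(layers = layers, config = config, head = head)
}

# Copy the shared trunk parameters (the leading conv/relu stack) from a
# trained checkpoint into a freshly built network. The in-package analogue
# of transfer learning: the presence classifier's trunk already encodes
# vertebra-relevant features, and reusing it stabilizes the corner nets'
# short training runs.
warm_start_trunk <- function(net, ckpt) {
  if (is.null(ckpt)) return(net)
  src <- ckpt$net$layers
  for (i in seq_len(min(6L, length(net$layers), length(src)))) {
    a <- net$layers[[i]]; b <- src[[i]]
    if (a$type != b$type) break
    if (a$type == "conv") {
      if (!all(dim(a$W) == dim(b$W))) break
      net$layers[[i]]$W <- b$W
      net$layers[[i]]$b <- b$b
    }
  }
  net
}

frozen_indices <- function(net) {
  fu <- net$config$freeze_until
  if (is.null(fu) || fu <= 0) return(integer(0))
  conv_idx <- which(vapply(net$layers, function(l) l$type == "conv", logical(1)))
  utils::head(conv_idx, fu)
}

# image matrix -> H x W x C input tensor (optionally with coordinate grids)
make_input <- function(pixels, coord_channels = TRUE) {
  h <- nrow(pixels); w <- ncol(pixels)
  if (!coord_channels) return(array(pixels, dim = c(h, w, 1L)))
  gx <- matrix(grid_coordinate(0:(w - 1), w), h, w, byrow = TRUE)
  gy <- matrix(grid_coordinate(0:(h - 1), h), h, w)
  array(c(pixels, gx, gy), dim = c(h, w, 3L))
}

# resize transform from an (w0, h0) frame into the square net input frame
resize_transform <- function(orig_size, input_size) {
  crop_transform(offset = c(0, 0),
                 scale = c(input_size / orig_size[1L], input_size / orig_size[2L]),
                 output_size = c(input_size, input_size))
}

# step-I tensors for one annotated image: input tensor, 96 x 2 normalized
# target block (rows ordered level-major, corner-minor) and its mask
prepare_step1 <- function(img, config) {
  s <- config$input_size
  tf <- resize_transform(image_size(img), s)
  x <- make_input(resize_image(img$pixels, s, s), config$coord_channels)
  target <- matrix(0, 96L, 2L)
  mask <- rep(FALSE, 96L)
  for (lev in names(img$landmarks)) {
    cs <- img$landmarks[[lev]]
    rows <- level_ordinal(lev) * 4L + 1:4
    ok <- cs$valid
    if (any(ok)) {
      target[rows[ok], ] <- normalize_coords(
        to_cropped(cs$points[ok, , drop = FALSE], tf), c(s, s))
      mask[rows[ok]] <- TRUE
    }
  }
  list(x = x, target = target, mask = mask,
       presence = as.numeric(presence_from_landmarks(img$landmarks)))
}

as_images <- function(set) {
  lapply(set, function(r) if (inherits(r, "ground_truth_record")) r$image else r)
}

# ---- training: presence classifier (CNN 1 analogue) ---------------------

#' Train the vertebra presence classifier
#'
#' Multi-label binary classification: for a whole (resized) radiograph,
#' predict for each of the 24 levels whether it is visible. Sigmoid
#' activations with binary cross-entropy, Adam, plateau LR decay, and
#' checkpointing of the lowest validation loss. The published full-scale
#' schedule is lr 1e-4, batch 16.
#'
#' @param train,val lists of `ground_truth_record` or [annotated_image()].
#' @param backbone a [backbone_config()].
#' @param schedule a [train_schedule()].
#' @param augment an [augment_config()] applied per epoch to training
#'   samples (caudal crop, rotation/flip, elastic, noise), or `NULL`.
#' @param seed seed for weight init, shuffling and augmentation.
#' @param verbose print per-epoch losses.
#' @return a checkpoint list (`net`, `history`, `kind = "presence"`, ...).
#' @export
train_presence <- function(train, val = list(),
                           backbone = backbone_config(),
                           schedule = train_schedule(learning_rate = 1e-4,
                                                     batch_size = 16L),
                           augment = NULL, seed = NULL, verbose = FALSE) {
  train <- as_images(train); val <- as_images(val)
  if (!length(train)) stop("empty training set", call. = FALSE)
  with_seed(seed, {
    net <- build_network(backbone, head = "presence")
    frozen <- frozen_indices(net)
    tensors <- function(img) {
      s <- backbone$input_size
      list(x = make_input(resize_image(img$pixels, s, s), backbone$coord_channels),
           presence = as.numeric(presence_from_landmarks(img$landmarks)))
    }
    fixed_train <- if (is.null(augment)) lapply(train, tensors) else train
    fixed_val <- lapply(val, tensors)
    step_fn <- function(net, sample) {
      sm <- if (is.null(augment)) sample else tensors(augment_full(sample, augment))
      fw <- net_forward(net, sm$x)
      l <- bce_loss_grad(fw$out, sm$presence)
      grads <- net_backward(net, fw$caches, l$dlogits)$grads
      grads[frozen] <- list(NULL)
      list(loss = l$loss, grads = grads)
    }
    val_fn <- function(net, sm) bce_loss_grad(net_forward(net, sm$x)$out, sm$presence)$loss
    fit <- train_loop(net, fixed_train, fixed_val, step_fn, val_fn, schedule,
                      verbose = verbose)
    structure(list(net = fit$net, backbone = backbone, schedule = schedule,
                   history = fit$history, best_val = fit$best_val,
                   kind = "presence"), class = "spinemark_checkpoint")
  })
}

# ---- training: global corner localizer (CNN 2 analogue) -----------------

#' Train the global corner localizer
#'
#' Heatmap regression over the whole resized radiograph: 96 heatmap
#' channels (24 levels x 4 corners), each collapsed to a coordinate by the
#' DSNT head, trained to minimize the masked mean Euclidean distance to the
#' normalized ground-truth corners. Levels absent from an image (and the
#' masked lower corners of S1) are excluded from the loss — the annotation
#' defines no target there. The published full-scale schedule is lr 1e-3,
#' batch 8.
#'
#' @inheritParams train_presence
#' @param warm_start optional checkpoint whose trunk convolutions initialize
#'   this network's trunk (in-package transfer learning).
#' @export
train_corners_global <- function(train, val = list(),
                                 backbone = backbone_config(heatmap_channels = 96L),
                                 schedule = train_schedule(learning_rate = 1e-3,
                                                           batch_size = 8L),
                                 augment = NULL, warm_start = NULL,
                                 seed = NULL, verbose = FALSE) {
  train <- as_images(train); val <- as_images(val)
  if (!length(train)) stop("empty training set", call. = FALSE)
  if (backbone$heatmap_channels != 96L) {
    stop("global localizer needs 96 heatmap channels (24 levels x 4 corners)",
         call. = FALSE)
  }
  with_seed(seed, {
    net <- warm_start_trunk(build_network(backbone, head = "heatmap"), warm_start)
    frozen <- frozen_indices(net)
    fixed_train <- if (is.null(augment)) lapply(train, prepare_step1, config = backbone)
                   else train
    fixed_val <- lapply(val, prepare_step1, config = backbone)
    pass <- function(net, sm, want_grads) {
      fw <- net_forward(net, sm$x)
      hd <- dsnt_forward(fw$out)
      l <- coord_loss_grad(hd$coords, sm$target, sm$mask)
      if (!want_grads) return(l$loss)
      dlogits <- dsnt_backward(hd, l$dpred)
      grads <- net_backward(net, fw$caches, dlogits)$grads
      grads[frozen] <- list(NULL)
      list(loss = l$loss, grads = grads)
    }
    step_fn <- function(net, sample) {
      sm <- if (is.null(augment)) sample
            else prepare_step1(augment_full(sample, augment), backbone)
      pass(net, sm, TRUE)
    }
    val_fn <- function(net, sm) pass(net, sm, FALSE)
    fit <- train_loop(net, fixed_train, fixed_val, step_fn, val_fn, schedule,
                      verbose = verbose)
    structure(list(net = fit$net, backbone = backbone, schedule = schedule,
                   history = fit$history, best_val = fit$best_val,
                   kind = "corners_global"), class = "spinemark_checkpoint")
  })
}

# ---- training: single-vertebra refiner (CNN 3 analogue) -----------------

# Build one refiner crop: extended bbox around the (possibly jittered)
# corners, crop-resize, targets mapped into the crop frame. Jitter emulates
# imperfect step-I boxes so the refiner generalizes to predicted crops.
refiner_crop <- function(img, level, input_size, extension = 0.7,
                         jitter = 0) {
  cs <- img$landmarks[[level]]
  pts <- valid_points(cs)
  ext <- extension
  if (jitter > 0) {
    ext <- max(0.2, extension + runif(1, -jitter, jitter))
    span <- apply(pts, 2L, function(v) diff(range(v)))
    pts <- sweep(pts, 2L, runif(2L, -jitter, jitter) * span, "+")
  }
  box <- padded_bbox(pts, ext, image_size(img))
  cr <- crop_resize(img$pixels, box, c(input_size, input_size))
  pm <- cs$points
  pm[cs$valid, ] <- to_cropped(cs$points[cs$valid, , drop = FALSE], cr$transform)
  crop_img <- annotated_image(
    cr$image, stats::setNames(list(corner_set(pmax(pm, 0), cs$valid)), level),
    paste0(img$image_id, "_", level))
  list(image = crop_img, transform = cr$transform)
}

# tight bbox grown by `extension`, with a minimum span so that the
# two-point S1 endplate still yields a usable crop
padded_bbox <- function(pts, extension, img_size, min_span = 6) {
  xr <- range(pts[, 1L]); yr <- range(pts[, 2L])
  grow <- function(r) {
    if (diff(r) < min_span) r <- mean(r) + c(-0.5, 0.5) * min_span
    r + c(-0.5, 0.5) * extension * diff(r)
  }
  xr <- grow(xr); yr <- grow(yr)
  clip_bbox(c(x_min = xr[1L], y_min = yr[1L], x_max = xr[2L], y_max = yr[2L]),
            img_size)
}

refiner_targets <- function(crop_img, input_size) {
  cs <- crop_img$landmarks[[1L]]
  target <- matrix(0, 4L, 2L)
  target[cs$valid, ] <- normalize_coords(valid_points(cs),
                                         c(input_size, input_size))
  list(target = target, mask = cs$valid)
}

#' Train the single-vertebra corner refiner
#'
#' The second step of the pipeline: the global corners define an extended
#' bounding box per vertebra (default +70% per side), the crop is resized to
#' a fixed square, and a single 4-channel DSNT head localizes the corners at
#' the finer effective pixel size. Training crops are built from
#' ground-truth corners with random box jitter so the network tolerates the
#' imperfect boxes produced by step I at inference time. The published
#' full-scale schedule is lr 1e-4, batch 16.
#'
#' @inheritParams train_presence
#' @param extension bounding-box growth fraction per side.
#' @param jitter relative box jitter applied to training crops.
#' @param augment an [augment_config()] applied to the crops (rotation,
#'   flip, elastic, noise — no caudal crop), or `NULL`.
#' @param warm_start optional checkpoint whose trunk convolutions initialize
#'   this network's trunk (in-package transfer learning).
#' @export
train_refiner <- function(train, val = list(),
                          backbone = backbone_config(heatmap_channels = 4L),
                          schedule = train_schedule(learning_rate = 1e-4,
                                                    batch_size = 16L),
                          augment = NULL, extension = 0.7, jitter = 0.35,
                          warm_start = NULL, seed = NULL, verbose = FALSE) {
  train <- as_images(train); val <- as_images(val)
  if (!length(train)) stop("empty training set", call. = FALSE)
  with_seed(seed, {
    net <- warm_start_trunk(build_network(backbone, head = "heatmap"), warm_start)
    frozen <- frozen_indices(net)
    s <- backbone$input_size
    # one sample per (image, annotated level)
    expand <- function(imgs) {
      out <- list()
      for (img in imgs) {
        for (lev in names(img$landmarks)) {
          if (n_valid_corners(img$landmarks[[lev]]) >= 2L) {
            out[[length(out) + 1L]] <- list(image = img, level = lev)
          }
        }
      }
      out
    }
    tensors <- function(pair, jit) {
      rc <- refiner_crop(pair$image, pair$level, s, extension, jit)
      crop_img <- rc$image
      if (!is.null(augment)) {
        crop_img <- elastic_and_noise(random_rotate_flip(crop_img, augment),
                                      augment)
      }
      tg <- refiner_targets(crop_img, s)
      list(x = make_input(crop_img$pixels, backbone$coord_channels),
           target = tg$target, mask = tg$mask)
    }
    train_pairs <- expand(train)
    dynamic <- !is.null(augment) || jitter > 0
    fixed_train <- if (dynamic) train_pairs else lapply(train_pairs, tensors, jit = 0)
    fixed_val <- lapply(expand(val), tensors, jit = 0)
    pass <- function(net, sm, want_grads) {
      fw <- net_forward(net, sm$x)
      hd <- dsnt_forward(fw$out)
      l <- coord_loss_grad(hd$coords, sm$target, sm$mask)
      if (!want_grads) return(l$loss)
      dlogits <- dsnt_backward(hd, l$dpred)
      grads <- net_backward(net, fw$caches, dlogits)$grads
      grads[frozen] <- list(NULL)
      list(loss = l$loss, grads = grads)
    }
    step_fn <- function(net, sample) {
      sm <- if (dynamic) tensors(sample, jitter) else sample
      pass(net, sm, TRUE)
    }
    val_fn <- function(net, sm) pass(net, sm, FALSE)
    fit <- train_loop(net, fixed_train, fixed_val, step_fn, val_fn, schedule,
                      verbose = verbose)
    structure(list(net = fit$net, backbone = backbone, schedule = schedule,
                   history = fit$history, best_val = fit$best_val,
                   extension = extension, kind = "refiner"),
              class = "spinemark_checkpoint")
  })
}

#' @export
print.spinemark_checkpoint <- function(x, ...) {
  cat(sprintf("<spinemark_checkpoint> %s (%s, input %d), %d epochs, best val loss %.5f\n",
              x$kind, x$backbone$family, x$backbone$input_size,
              nrow(x$history), x$best_val))
  invisible(x)
}

# ---- two-step inference -------------------------------------------------

#' Run the two-step pipeline on a radiograph
#'
#' Step I: the image is resized to the networks' input size and normalized;
#' the presence classifier selects the levels with probability at or above
#' `threshold`; the global localizer's DSNT blocks are read at those level
#' indices and denormalized back to original-image pixels. Step II: each
#' detected vertebra is cropped with an extended bounding box, the refiner
#' localizes its 4 corners in the crop, and the inverse crop transform maps
#' them to the original frame. If refinement fails for a level, its step-I
#' corners are kept (provenance `"step-I-only"`).
#'
#' @param image numeric matrix in `[0, 1]` or an [annotated_image()].
#' @param presence_ckpt,global_ckpt,refiner_ckpt checkpoints from the three
#'   training functions.
#' @param threshold presence probability threshold (default 0.5).
#' @param refine set `FALSE` to stop after step I.
#' @param contiguity_filter optionally keep only the longest contiguous run
#'   of detected levels (off by default; the full-scale model evidently did
#'   not enforce contiguity, as it reports missed mid-column vertebrae).
#' @return list of detections, each with `level`, `presence_prob`,
#'   `corners` ([corner_set()] in original pixels), `provenance` and, for
#'   refined detections, the audit `crop_transform`. Empty list when
#'   nothing exceeds the threshold.
#' @export
infer <- function(image, presence_ckpt, global_ckpt, refiner_ckpt = NULL,
                  threshold = 0.5, refine = TRUE, contiguity_filter = FALSE) {
  pixels <- if (inherits(image, "annotated_image")) image$pixels else image
  pixels <- normalize_intensity(pixels)
  orig_size <- c(ncol(pixels), nrow(pixels))

  run_resized <- function(ckpt) {
    s <- ckpt$backbone$input_size
    x <- make_input(resize_image(pixels, s, s), ckpt$backbone$coord_channels)
    list(out = net_forward(ckpt$net, x)$out, size = s)
  }
  pres <- run_resized(presence_ckpt)
  probs <- sigmoid(pres$out)
  detected <- which(probs >= threshold)
  if (contiguity_filter && length(detected)) {
    runs <- split(detected, cumsum(c(1, diff(detected) != 1)))
    detected <- runs[[which.max(lengths(runs))]]
  }
  if (!length(detected)) return(list())

  glob <- run_resized(global_ckpt)
  hd <- dsnt_forward(glob$out)
  tf1 <- resize_transform(orig_size, glob$size)
  corners_all <- to_original(denormalize(hd$coords, c(glob$size, glob$size)), tf1)

  out <- list()
  for (ord in detected - 1L) {
    lev <- ordinal_level(ord)
    rows <- ord * 4L + 1:4
    pts <- corners_all[rows, , drop = FALSE]
    valid <- if (lev == "S1") c(TRUE, TRUE, FALSE, FALSE) else rep(TRUE, 4L)
    pts[, 1L] <- pmin(pmax(pts[, 1L], 0), orig_size[1L] - 1)
    pts[, 2L] <- pmin(pmax(pts[, 2L], 0), orig_size[2L] - 1)
    cs1 <- corner_set(ifelse(cbind(valid, valid), pts, NA), valid)
    det <- list(level = lev, presence_prob = unname(probs[ord + 1L]),
                corners = cs1, corners_step1 = cs1,
                provenance = "step-I-only", crop_transform = NULL)
    if (refine && !is.null(refiner_ckpt)) {
      det <- tryCatch({
        s2 <- refiner_ckpt$backbone$input_size
        ext <- if (is.null(refiner_ckpt$extension)) 0.7 else refiner_ckpt$extension
        box <- padded_bbox(pts[valid, , drop = FALSE], ext, orig_size)
        cr <- crop_resize(pixels, box, c(s2, s2))
        x <- make_input(cr$image, refiner_ckpt$backbone$coord_channels)
        rc <- dsnt_forward(net_forward(refiner_ckpt$net, x)$out)
        ref <- to_original(denormalize(rc$coords, c(s2, s2)), cr$transform)
        ref[, 1L] <- pmin(pmax(ref[, 1L], 0), orig_size[1L] - 1)
        ref[, 2L] <- pmin(pmax(ref[, 2L], 0), orig_size[2L] - 1)
        det$corners <- corner_set(ifelse(cbind(valid, valid), ref, NA), valid)
        det$provenance <- "refined"
        det$crop_transform <- cr$transform
        det
      }, error = function(e) det)
    }
    out[[length(out) + 1L]] <- det
  }
  out
}

#' Convert a detection list to a landmark map
#'
#' @param detections output of [infer()].
#' @return named list of [corner_set()] keyed by level, directly usable by
#'   [angles_from_corners()] and the evaluation suite.
#' @export
detections_to_landmarks <- function(detections) {
  stats::setNames(lapply(detections, `[[`, "corners"),
                  vapply(detections, `[[`, character(1), "level"))
}
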