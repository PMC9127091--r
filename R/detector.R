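#' Training configuration
#'
#' Defaults follow the reference training recipe: 700 iterative cycles,
#' batch size 8, SGD momentum 0.9, learning rate 0.001 reduced by a factor
#' of 10 after 400 cycles, confidence threshold 0.5 and NMS threshold 0.3
#' at evaluation time, with the model evaluated every 10 cycles and the
#' checkpoint with the best validation mAP retained.
#'
#' @param iterations Number of training cycles (mini-batch steps).
#' @param batch_size Images per cycle.
#' @param momentum SGD momentum.
#' @param learning_rate Initial learning rate.
#' @param lr_drop_at Cycle after which the learning rate is multiplied by
#'   `lr_drop_factor`.
#' @param lr_drop_factor Learning-rate reduction factor.
#' @param input_size Network input side in pixels.
#' @param width_multiplier Channel-profile fraction for the backbone.
#' @param seed Integer seed governing weight init and batch sampling.
#' @param eval_every Evaluate validation mAP every this many cycles.
#' @param eval_n Maximum validation images per evaluation.
#' @param clip_norm Global gradient-norm clip.
#' @param loss_weights Length-3 weights (position, confidence,
#'   classification).
#' @param augment Apply random geometric augmentation (quarter turns and
#'   flips, with labels transformed consistently) to each training image
#'   draw, per the image-enhancement protocol.
#' @return A list of class `fy_train_config`.
#' @export
train_config <- function(iterations = 700L, batch_size = 8L, momentum = 0.9,
                         learning_rate = 0.001, lr_drop_at = 400L,
                         lr_drop_factor = 0.1, input_size = 416L,
                         width_multiplier = 1, seed = 1L, eval_every = 10L,
                         eval_n = 16L, clip_norm = 25,
                         loss_weights = c(1, 1, 1), augment = TRUE) {
  stopifnot(iterations > 0, batch_size > 0, momentum >= 0,
            learning_rate >= 0, lr_drop_at > 0, lr_drop_factor > 0)
  if (lr_drop_at >= iterations) lr_drop_at <- iterations  # never triggers
  structure(list(iterations = as.integer(iterations),
                 batch_size = as.integer(batch_size), momentum = momentum,
                 learning_rate = learning_rate,
                 lr_drop_at = as.integer(lr_drop_at),
                 lr_drop_factor = lr_drop_factor,
                 input_size = as.integer(input_size),
                 width_multiplier = width_multiplier,
                 seed = as.integer(seed), eval_every = as.integer(eval_every),
                 eval_n = as.integer(eval_n), clip_norm = clip_norm,
                 loss_weights = loss_weights, augment = isTRUE(augment)),
            class = "fy_train_config")
}

#' Desk-scale training configuration
#'
#' The reduced recipe used for CPU-scale experiments and the package's
#' smoke runs: 128-pixel inputs, a 0.25 width multiplier, 300 cycles at a
#' learning rate of 0.008 dropped 10x late in training, with checkpoint
#' selection on the full validation split. The higher rate (relative to
#' the full-scale default of 0.001) suits the much smaller normalized
#' network; the late drop settles the oscillation of the final cycles
#' before the best-by-validation checkpoint is taken.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [train_config()].
#' @return An `fy_train_config`.
#' @export
toy_train_config <- function(seed = 7L, ...) {
  args <- list(iterations = 300L, batch_size = 8L, input_size = 128L,
               width_multiplier = 0.25, learning_rate = 0.008,
               lr_drop_at = 240L, lr_drop_factor = 0.1, eval_n = 64L,
               seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(train_config, args)
}

#' Load and resize an image for the network
#'
#' Reads (if given a path) and stretches the image to
#' `input_size x input_size` by bilinear interpolation, with channel values
#' in `[0, 1]`. Direct stretch (not letterboxing) is used, so normalized
#' label coordinates remain valid unchanged.
#'
#' @param image An `H x W x 3` array in `[0, 1]`, or a PNG file path.
#' @param input_size Target side in pixels.
#' @return An `input_size x input_size x 3` array.
#' @export
preprocess <- function(image, input_size = 416L) {
  if (is.character(image)) image <- png::readPNG(image)
  if (length(dim(image)) == 2L) {
    image <- array(rep(image, 3L), dim = c(dim(image), 3L))
  }
  if (dim(image)[3] > 3L) image <- image[, , 1:3, drop = FALSE]
  if (any(dim(image)[1:2] == 0L)) stop("I/O error: empty image", call. = FALSE)
  if (!all(dim(image)[1:2] == input_size)) {
    image <- EBImage::resize(image, w = input_size, h = input_size)
  }
  array(clamp(image, 0, 1), dim = c(input_size, input_size, 3L))
}

load_manifest_images <- function(manifest, input_size, split = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (!is.null(split)) manifest <- manifest[manifest$split == split, , drop = FALSE]
  if (nrow(manifest) == 0L) stop("data error: empty manifest", call. = FALSE)
  list(
    images = lapply(manifest$image_path, preprocess, input_size = input_size),
    labels = lapply(manifest$label_path, read_yolo_labels),
    manifest = manifest
  )
}

#' Train the detector
#'
#' SGD with momentum over mini-batches sampled from the manifest's training
#' split, with per-cycle loss tracing, a step learning-rate schedule, and
#' periodic validation mAP evaluation; the parameters with the best
#' validation mAP are returned in the checkpoint. Gradients are averaged
#' over the batch and clipped in global norm.
#'
#' @param manifest A manifest data frame (or TSV path) with columns
#'   `image_path, label_path, split, regime`.
#' @param anchors An `fy_anchors` fitted to the training labels.
#' @param config An [train_config()] object.
#' @param loss_mode `"giou"` or `"euclidean"` position loss.
#' @param quiet Suppress progress messages.
#' @return A checkpoint of class `fy_checkpoint`: `net`, `anchors`, `spec`,
#'   `config`, `loss_mode`, `trace` (per-cycle loss terms data frame),
#'   `best_iter`, `best_map`.
#' @export
train_detector <- function(manifest, anchors, config = train_config(),
                           loss_mode = c("giou", "euclidean"), quiet = FALSE) {
  loss_mode <- match.arg(loss_mode)
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  train <- load_manifest_images(manifest, config$input_size, split = "train")
  val_rows <- manifest[manifest$split == "test", , drop = FALSE]
  has_val <- nrow(val_rows) > 0L
  if (has_val && nrow(val_rows) > config$eval_n) {
    val_rows <- val_rows[seq_len(config$eval_n), , drop = FALSE]
  }
  val <- if (has_val) load_manifest_images(val_rows, config$input_size) else NULL

  net <- build_backbone(config$input_size, config$width_multiplier,
                        seed = config$seed)
  spec <- net$spec
  targets <- lapply(train$labels, encode_targets, spec = spec,
                    anchors = anchors)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed + 1L)
  n <- length(train$images)
  order_pool <- sample.int(n)
  pool_pos <- 1L
  velocity <- zero_like_params(net$params)
  trace <- data.frame(iter = integer(0), position = numeric(0),
                      confidence = numeric(0), classification = numeric(0),
                      total = numeric(0), lr = numeric(0))
  best <- list(params = net$params, map = -Inf, iter = 0L)

  for (it in seq_len(config$iterations)) {
    lr <- config$learning_rate *
      if (it > config$lr_drop_at) config$lr_drop_factor else 1
    # draw a batch from a reshuffled epoch pool
    batch <- integer(0)
    while (length(batch) < config$batch_size) {
      take <- min(config$batch_size - length(batch), n - pool_pos + 1L)
      batch <- c(batch, order_pool[pool_pos:(pool_pos + take - 1L)])
      pool_pos <- pool_pos + take
      if (pool_pos > n) { order_pool <- sample.int(n); pool_pos <- 1L }
    }
    acc <- zero_like_params(net$params)
    terms <- c(position = 0, confidence = 0, classification = 0)
    for (bi in batch) {
      img <- train$images[[bi]]
      tgt <- targets[[bi]]
      if (config$augment) {
        aug <- list(image = img, labels = train$labels[[bi]])
        if (stats::runif(1) < 0.5) aug <- augment(aug$image, aug$labels, "hflip")
        if (stats::runif(1) < 0.5) aug <- augment(aug$image, aug$labels, "vflip")
        if (stats::runif(1) < 0.5) aug <- augment(aug$image, aug$labels, "rotate90")
        img <- aug$image
        tgt <- encode_targets(aug$labels, spec, anchors)
      }
      fw <- net_forward(net, img, keep_cache = TRUE)
      lg <- yolo_loss_grad(fw$raw, tgt, spec, anchors, loss_mode,
                           config$loss_weights, want_grad = TRUE)
      terms <- terms + c(lg$terms$position, lg$terms$confidence,
                         lg$terms$classification)
      acc <- accumulate_grads(acc, net_backward(net, fw$cache, lg$grads))
    }
    acc <- scale_grads(acc, 1 / length(batch))
    terms <- terms / length(batch)
    tot <- sum(terms)
    if (!is.finite(tot)) {
      stop(sprintf("divergence error: non-finite loss at iteration %d", it),
           call. = FALSE)
    }
    st <- sgd_step(net, acc, velocity, lr, config$momentum, config$clip_norm)
    net <- st$net; velocity <- st$velocity
    trace <- rbind(trace, data.frame(iter = it, position = terms[1],
                                     confidence = terms[2],
                                     classification = terms[3], total = tot,
                                     lr = lr))
    if (has_val && (it %% config$eval_every == 0L || it == config$iterations)) {
      m <- quick_map(net, anchors, val)
      if (m > best$map) best <- list(params = net$params, map = m, iter = it)
      if (!quiet) {
        message(sprintf("iter %4d  loss %8.3f  val mAP %.3f  (best %.3f @ %d)",
                        it, tot, m, best$map, best$iter))
      }
    } else if (!quiet && it %% 25L == 0L) {
      message(sprintf("iter %4d  loss %8.3f", it, tot))
    }
  }
  if (!has_val || !is.finite(best$map)) best <- list(params = net$params,
                                                     map = NA_real_,
                                                     iter = config$iterations)
  net$params <- best$params
  rownames(trace) <- NULL
  structure(list(net = net, anchors = anchors, spec = spec, config = config,
                 loss_mode = loss_mode, trace = trace,
                 best_iter = best$iter, best_map = best$map),
            class = "fy_checkpoint")
}

# lightweight validation mAP on preloaded images
quick_map <- function(net, anchors, val, conf = 0.5, nms_iou = 0.3) {
  dets <- lapply(val$images, function(img) {
    fw <- net_forward(net, img)
    nms(filter_confidence(decode_raw(fw$raw, net$spec, anchors), conf),
        nms_iou)
  })
  mean_average_precision(dets, val$labels, n_classes = net$spec$C)$mAP
}

#' Run inference on images
#'
#' Forward pass, decode, confidence filtering and per-class NMS for each
#' image.
#'
#' @param checkpoint An `fy_checkpoint` (or RDS path from
#'   [save_checkpoint()]).
#' @param images A list of image arrays or file paths.
#' @param conf_threshold Confidence threshold (default 0.5).
#' @param nms_iou NMS suppression threshold (default 0.3).
#' @return A list of per-image detection data frames
#'   (`class, cx, cy, w, h, confidence`).
#' @export
infer_images <- function(checkpoint, images, conf_threshold = 0.5,
                         nms_iou = 0.3) {
  if (is.character(checkpoint)) checkpoint <- load_checkpoint(checkpoint)
  if (!is.list(images) || is.array(images)) images <- list(images)
  lapply(images, function(img) {
    x <- preprocess(img, checkpoint$spec$input_size)
    fw <- net_forward(checkpoint$net, x)
    cands <- decode_raw(fw$raw, checkpoint$spec, checkpoint$anchors)
    nms(filter_confidence(cands, conf_threshold), nms_iou)
  })
}

#' Save / load a checkpoint
#'
#' Checkpoints are self-describing: they carry the network weights, the
#' anchor set, the grid spec and the training configuration.
#'
#' @param checkpoint An `fy_checkpoint`.
#' @param path File path.
#' @export
save_checkpoint <- function(checkpoint, path) {
  stopifnot(inherits(checkpoint, "fy_checkpoint"))
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  stopifnot(inherits(ck, "fy_checkpoint"))
  ck
}
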