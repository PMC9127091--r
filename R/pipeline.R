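#' Default run configuration
#'
#' Plain-list (YAML-serializable) configuration for [run_pipeline()].
#' Training defaults follow the reference recipe (700 cycles, batch 8,
#' momentum 0.9, learning rate 0.001 dropped 10x after 400 cycles) and the
#' post-processing defaults are confidence 0.5 and NMS IoU 0.3; every
#' override is logged when the pipeline runs.
#'
#' @param out_dir Artifact directory.
#' @param ... Named overrides merged (recursively) over the defaults.
#' @return A nested list of class `fy_run_config`.
#' @export
default_run_config <- function(out_dir = "fy_run", ...) {
  cfg <- list(
    out_dir = out_dir,
    seed = 1L,
    input_size = 416L,
    width_multiplier = 1,
    generate = list(enabled = TRUE, n_images = 30L,
                    mix = list(sparse = 1 / 3, dense = 1 / 3, occluded = 1 / 3),
                    test_fraction = 0.25, count_range = c(2L, 6L)),
    anchors = list(fit = TRUE, k = 9L, restarts = 10L),
    train = list(iterations = 700L, batch_size = 8L, momentum = 0.9,
                 learning_rate = 0.001, lr_drop_at = 400L,
                 lr_drop_factor = 0.1, eval_every = 10L, eval_n = 16L),
    loss = list(position = "giou"),
    post = list(confidence = 0.5, nms_iou = 0.3),
    manifest = NULL
  )
  structure(merge_config(cfg, list(...)), class = "fy_run_config")
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a run configuration from YAML
#'
#' Values absent from the file take the package defaults; overrides of the
#' training defaults are reported when the pipeline runs.
#'
#' @param path YAML file path.
#' @return An `fy_run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_run_config()
  structure(merge_config(unclass(cfg), raw), class = "fy_run_config")
}

#' Run the full detection pipeline
#'
#' Executes generate (optional) -> anchor fit -> train -> infer -> evaluate,
#' persisting each stage's artifact under `config$out_dir` (`manifest.tsv`
#' via the data directory, `anchors.yaml`, `checkpoint.rds`,
#' `loss_trace.csv`, `detections.json`, `report.json`). Existing artifacts
#' are reused unless `overwrite = TRUE`, making every stage resumable.
#'
#' @param config An `fy_run_config` (or YAML path).
#' @param overwrite Recompute stages whose artifacts already exist.
#' @param quiet Suppress progress messages.
#' @return A list with the five artifact paths plus the evaluation report.
#' @export
run_pipeline <- function(config = default_run_config(), overwrite = FALSE,
                         quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    say("[%s] done in %.1f s", name, proc.time()[["elapsed"]] - t0)
    r
  }
  say("run_pipeline: seed %d, input %d px, loss '%s'",
      config$seed, config$input_size, config$loss$position)

  manifest_path <- if (!is.null(config$manifest)) config$manifest else
    file.path(config$out_dir, "data", "manifest.tsv")
  if (isTRUE(config$generate$enabled) &&
      (overwrite || !file.exists(manifest_path))) {
    stage("generate", generate_dataset(
      n_images = config$generate$n_images,
      out_dir = dirname(manifest_path),
      mix = unlist(config$generate$mix),
      image_size = config$input_size,
      test_fraction = config$generate$test_fraction,
      count_range = config$generate$count_range,
      seed = config$seed))
  }
  if (!file.exists(manifest_path)) {
    stop("config error: no manifest at '", manifest_path,
         "' and generate.enabled is false", call. = FALSE)
  }
  manifest <- read_manifest(manifest_path)

  anchors_path <- file.path(config$out_dir, "anchors.yaml")
  if (overwrite || !file.exists(anchors_path)) {
    if (!isTRUE(config$anchors$fit)) {
      stop("config error: anchors.fit is false but no anchors file at '",
           anchors_path, "'", call. = FALSE)
    }
    anchors <- stage("anchors", {
      train_rows <- manifest[manifest$split == "train", , drop = FALSE]
      sizes <- do.call(rbind, lapply(train_rows$label_path, function(p) {
        l <- read_yolo_labels(p)
        cbind(l$w, l$h) * config$input_size
      }))
      fit <- kmeans_anchors(sizes, k = config$anchors$k, seed = config$seed,
                            restarts = config$anchors$restarts)
      spec <- grid_spec(config$input_size)
      allocate_to_scales(fit$sizes, spec$S)
    })
    write_anchors(anchors, anchors_path)
  } else {
    anchors <- read_anchors(anchors_path)
  }

  ckpt_path <- file.path(config$out_dir, "checkpoint.rds")
  if (overwrite || !file.exists(ckpt_path)) {
    tc <- train_config(iterations = config$train$iterations,
                       batch_size = config$train$batch_size,
                       momentum = config$train$momentum,
                       learning_rate = config$train$learning_rate,
                       lr_drop_at = config$train$lr_drop_at,
                       lr_drop_factor = config$train$lr_drop_factor,
                       input_size = config$input_size,
                       width_multiplier = config$width_multiplier,
                       seed = config$seed,
                       eval_every = config$train$eval_every,
                       eval_n = config$train$eval_n)
    ckpt <- stage("train", train_detector(manifest, anchors, tc,
                                          loss_mode = config$loss$position,
                                          quiet = quiet))
    save_checkpoint(ckpt, ckpt_path)
    utils::write.csv(ckpt$trace,
                     file.path(config$out_dir, "loss_trace.csv"),
                     row.names = FALSE)
  } else {
    ckpt <- load_checkpoint(ckpt_path)
  }

  det_path <- file.path(config$out_dir, "detections.json")
  test_rows <- manifest[manifest$split == "test", , drop = FALSE]
  if (nrow(test_rows) == 0L) test_rows <- manifest
  if (overwrite || !file.exists(det_path)) {
    dets <- stage("infer", infer_images(
      ckpt, as.list(test_rows$image_path),
      conf_threshold = config$post$confidence,
      nms_iou = config$post$nms_iou))
    write_detections(dets, test_rows$image_path, det_path)
  } else {
    dets <- read_detections(det_path)$detections
  }

  report_path <- file.path(config$out_dir, "report.json")
  report <- stage("evaluate", evaluate_detections(dets, test_rows))
  jsonlite::write_json(
    list(mAP = report$mAP, ap = report$ap, counts = report$counts),
    report_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")

  list(manifest = manifest_path, anchors = anchors_path,
       checkpoint = ckpt_path, detections = det_path, report = report_path,
       evaluation = report)
}

#' Write / read per-image detections as JSON
#'
#' One record per image: the image path, a list of
#' `{class, cx, cy, w, h, confidence}` detections, and the per-class
#' counts.
#'
#' @param dets_list List of detection data frames.
#' @param image_paths Character vector aligned with `dets_list`.
#' @param path Output JSON path.
#' @export
write_detections <- function(dets_list, image_paths, path) {
  recs <- Map(function(d, p) {
    d <- d[, c("class", "cx", "cy", "w", "h", "confidence"), drop = FALSE]
    list(image = p, detections = d, counts = as.list(count_fruits(d)))
  }, dets_list, image_paths)
  jsonlite::write_json(unname(recs), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_detections
#' @return `read_detections()` returns a list with `detections` (list of
#'   data frames) and `images` (paths).
#' @export
read_detections <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = TRUE,
                              simplifyDataFrame = TRUE)
  dets <- lapply(recs$detections, function(d) {
    if (is.null(d) || length(d) == 0L || nrow(as.data.frame(d)) == 0L) {
      data.frame(class = integer(0), cx = numeric(0), cy = numeric(0),
                 w = numeric(0), h = numeric(0), confidence = numeric(0))
    } else {
      as.data.frame(d)
    }
  })
  list(detections = dets, images = recs$image)
}
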