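#' Match one image's detections against ground truth
#'
#' Greedy matching by descending confidence: a detection is a true positive
#' if its best-overlapping unmatched same-class truth box has
#' `IoU >= iou_threshold`; each truth is matched at most once; everything
#' else is a false positive. Confidence ties follow the NMS rule (larger
#' area first, then input order).
#'
#' @param dets Detection data frame (`class, cx, cy, w, h, confidence`).
#' @param truths Label data frame (`class, cx, cy, w, h`).
#' @param iou_threshold Matching threshold (default 0.5).
#' @return A data frame `class, confidence, area, tp` with one row per
#'   detection.
#' @export
match_detections <- function(dets, truths, iou_threshold = 0.5) {
  if (nrow(dets) == 0L) {
    return(data.frame(class = integer(0), confidence = numeric(0),
                      area = numeric(0), tp = logical(0)))
  }
  area <- dets$w * dets$h
  ord <- order(-dets$confidence, -area, seq_len(nrow(dets)))
  dets <- dets[ord, , drop = FALSE]
  area <- area[ord]
  matched <- rep(FALSE, nrow(truths))
  tp <- logical(nrow(dets))
  db <- as_box_matrix(dets)
  tb <- if (nrow(truths)) as_box_matrix(truths) else NULL
  for (i in seq_len(nrow(dets))) {
    cand <- which(!matched & truths$class == dets$class[i])
    if (length(cand) == 0L) next
    ious <- box_iou(db[rep(i, length(cand)), , drop = FALSE],
                    tb[cand, , drop = FALSE])
    j <- which.max(ious)
    if (ious[j] >= iou_threshold) {
      tp[i] <- TRUE
      matched[cand[j]] <- TRUE
    }
  }
  data.frame(class = dets$class, confidence = dets$confidence,
             area = area, tp = tp)
}

#' Average precision from matched detection flags
#'
#' All-point interpolated area under the precision-recall curve: flags are
#' sorted by descending confidence (ties by larger area then input order),
#' precision is replaced by its running maximum from the right (the
#' precision envelope), and the area is accumulated over recall increments.
#'
#' @param flags Data frame from [match_detections()] (one class), with
#'   columns `confidence, area, tp`.
#' @param n_truth Number of ground-truth objects of the class; must be
#'   positive.
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(flags, n_truth) {
  if (n_truth <= 0L) {
    stop("undefined AP: no ground-truth objects for this class", call. = FALSE)
  }
  if (nrow(flags) == 0L) return(0)
  ord <- order(-flags$confidence, -flags$area, seq_len(nrow(flags)))
  tp <- flags$tp[ord]
  cum_tp <- cumsum(tp)
  precision <- cum_tp / seq_along(tp)
  recall <- cum_tp / n_truth
  # precision envelope (non-increasing from the right)
  env <- rev(cummax(rev(precision)))
  sum(diff(c(0, recall)) * env)
}

#' Mean average precision over a set of images
#'
#' Pools detections across images, computes per-class AP at the given IoU
#' threshold and averages over the classes present in the ground truth.
#'
#' @param dets_list List of per-image detection data frames.
#' @param truths_list List of per-image label data frames (same order).
#' @param n_classes Number of classes.
#' @param iou_threshold Matching threshold (default 0.5).
#' @return A list: `mAP`, `ap` (per-class vector, `NA` for classes with no
#'   truth).
#' @export
mean_average_precision <- function(dets_list, truths_list, n_classes = 2L,
                                   iou_threshold = 0.5) {
  stopifnot(length(dets_list) == length(truths_list))
  flags <- do.call(rbind, Map(match_detections, dets_list, truths_list,
                              MoreArgs = list(iou_threshold = iou_threshold)))
  ap <- rep(NA_real_, n_classes)
  for (cl in seq_len(n_classes) - 1L) {
    n_truth <- sum(vapply(truths_list, function(t) sum(t$class == cl), 0L))
    if (n_truth == 0L) next
    ap[cl + 1L] <- average_precision(flags[flags$class == cl, , drop = FALSE],
                                     n_truth)
  }
  list(mAP = mean(ap, na.rm = TRUE), ap = ap)
}

#' Yield-estimation accuracy report
#'
#' The yield-estimation accuracy is the detector's fruit count divided by
#' the manual (reference) count, expressed as a percentage, per class (red,
#' green) and in total — overall and per viewing regime when regime tags
#' are supplied. The raw ratio is reported (overcounting can exceed 100%)
#' together with the symmetric error `|100 - accuracy|`.
#'
#' @param model_counts Data frame (or matrix) with columns `n_red, n_green`,
#'   one row per image, from the detector.
#' @param reference_counts Same shape, from the ground-truth labels.
#' @param regimes Optional character vector of per-image regime tags.
#' @return A data frame of class `fy_count_report` with columns
#'   `regime, class, model, reference, accuracy_pct, abs_error_pct`.
#' @export
yield_accuracy <- function(model_counts, reference_counts, regimes = NULL) {
  mc <- as.data.frame(model_counts)
  rc <- as.data.frame(reference_counts)
  stopifnot(nrow(mc) == nrow(rc))
  if (is.null(regimes)) regimes <- rep("all", nrow(mc))
  groups <- c(unique(as.character(regimes)), "overall")
  rows <- lapply(groups, function(g) {
    sel <- if (g == "overall") rep(TRUE, nrow(mc)) else regimes == g
    m <- c(red = sum(mc$n_red[sel]), green = sum(mc$n_green[sel]))
    r <- c(red = sum(rc$n_red[sel]), green = sum(rc$n_green[sel]))
    m <- c(m, total = sum(m)); r <- c(r, total = sum(r))
    acc <- numeric(3)
    for (k in 1:3) {
      if (r[k] == 0 && m[k] > 0) {
        warning(sprintf("overcount with zero reference (%s, %s): ratio taken against 1",
                        g, names(m)[k]), call. = FALSE)
      }
      acc[k] <- 100 * m[k] / max(r[k], 1)
    }
    data.frame(regime = g, class = names(m), model = as.integer(m),
               reference = as.integer(r),
               accuracy_pct = round(acc, 1),
               abs_error_pct = round(abs(100 - acc), 1))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("fy_count_report", class(out))
  out
}

#' Evaluate detections against a manifest
#'
#' Computes mAP and the yield-accuracy report (overall and per regime) for
#' a set of per-image detections against the manifest's label files.
#'
#' @param dets_list List of per-image detection data frames, aligned with
#'   the manifest rows.
#' @param manifest Manifest data frame (or TSV path); typically the test
#'   split.
#' @param n_classes Number of classes.
#' @param iou_threshold mAP matching threshold.
#' @return A list of class `fy_eval`: `mAP`, `ap`, `counts`
#'   (the `fy_count_report`).
#' @export
evaluate_detections <- function(dets_list, manifest, n_classes = 2L,
                                iou_threshold = 0.5) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(length(dets_list) == nrow(manifest))
  truths <- lapply(manifest$label_path, read_yolo_labels)
  m <- mean_average_precision(dets_list, truths, n_classes, iou_threshold)
  mcount <- do.call(rbind, lapply(dets_list, function(d) {
    k <- count_fruits(d); data.frame(n_red = k[["n_red"]], n_green = k[["n_green"]])
  }))
  rcount <- do.call(rbind, lapply(truths, function(t) {
    data.frame(n_red = sum(t$class == 0L), n_green = sum(t$class == 1L))
  }))
  counts <- yield_accuracy(mcount, rcount, regimes = manifest$regime)
  structure(list(mAP = m$mAP, ap = m$ap, counts = counts), class = "fy_eval")
}

#' @export
print.fy_eval <- function(x, ...) {
  cat(sprintf("mAP@0.5: %.3f  (per-class AP: %s)\n", x$mAP,
              paste(sprintf("%.3f", x$ap), collapse = ", ")))
  print.data.frame(x$counts)
  invisible(x)
}
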