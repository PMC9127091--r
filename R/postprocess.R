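#' Filter candidate detections by confidence
#'
#' Keeps detections with `confidence >= threshold` (inclusive), preserving
#' input order.
#'
#' @param cands Detection data frame with columns
#'   `class, cx, cy, w, h, confidence`.
#' @param threshold Confidence threshold in `[0, 1]` (default 0.5).
#' @return The filtered data frame.
#' @export
filter_confidence <- function(cands, threshold = 0.5) {
  stopifnot(threshold >= 0, threshold <= 1)
  cands[cands$confidence >= threshold, , drop = FALSE]
}

#' Greedy per-class non-maximum suppression
#'
#' Within each class independently: repeatedly keep the highest-confidence
#' remaining box and suppress all boxes of that class whose IoU with a kept
#' box strictly exceeds `iou_threshold`. Confidence ties are broken in
#' favor of the larger-area box, then input order. Red and green fruit are
#' distinct count targets, so boxes of different classes never suppress one
#' another.
#'
#' @param cands Confidence-filtered detection data frame.
#' @param iou_threshold Suppression threshold (default 0.3); overlap equal
#'   to the threshold is not suppressed.
#' @return The kept detections, ordered by class then descending
#'   confidence.
#' @export
nms <- function(cands, iou_threshold = 0.3) {
  if (nrow(cands) == 0L) return(cands)
  out <- lapply(sort(unique(cands$class)), function(cl) {
    d <- cands[cands$class == cl, , drop = FALSE]
    area <- d$w * d$h
    ord <- order(-d$confidence, -area, seq_len(nrow(d)))
    d <- d[ord, , drop = FALSE]
    boxes <- as_box_matrix(d)
    keep <- logical(nrow(d))
    alive <- rep(TRUE, nrow(d))
    for (i in seq_len(nrow(d))) {
      if (!alive[i]) next
      keep[i] <- TRUE
      if (i < nrow(d)) {
        rest <- which(alive & seq_len(nrow(d)) > i)
        if (length(rest)) {
          ious <- box_iou(boxes[rep(i, length(rest)), , drop = FALSE],
                          boxes[rest, , drop = FALSE])
          alive[rest[ious > iou_threshold]] <- FALSE
        }
      }
    }
    d[keep, , drop = FALSE]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Count fruits in a set of final detections
#'
#' @param dets Post-NMS detection data frame (class 0 = red, 1 = green).
#' @return A named integer vector `(n_red, n_green, n_total)`.
#' @export
count_fruits <- function(dets) {
  n_red <- sum(dets$class == 0L)
  n_green <- sum(dets$class == 1L)
  c(n_red = n_red, n_green = n_green, n_total = n_red + n_green)
}
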