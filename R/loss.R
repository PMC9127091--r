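#' Euclidean position loss over matched box pairs
#'
#' The classical grid-detector location loss: for each responsible
#' (cell, prior) pair, the squared center offset plus the squared
#' difference of square-rooted sizes,
#' `(x - x')^2 + (y - y')^2 + (sqrt(w) - sqrt(w'))^2 + (sqrt(h) - sqrt(h'))^2`,
#' summed over pairs. This loss is scale-dependent: jointly rescaling a
#' pred/truth pair changes its value, which is the motivation for the GIoU
#' alternative.
#'
#' @param pred,truth Aligned box sets (normalized units), one pair per
#'   responsible slot.
#' @return Non-negative scalar.
#' @export
euclidean_position_loss <- function(pred, truth) {
  p <- as_box_matrix(pred); t <- as_box_matrix(truth)
  if (nrow(p) != nrow(t)) {
    stop("alignment error: pred and truth lists differ in length", call. = FALSE)
  }
  validate_boxes(p); validate_boxes(t)
  sum((p[, 1] - t[, 1])^2 + (p[, 2] - t[, 2])^2 +
      (sqrt(p[, 3]) - sqrt(t[, 3]))^2 + (sqrt(p[, 4]) - sqrt(t[, 4]))^2)
}

#' GIoU position loss over matched box pairs
#'
#' `sum(1 - giou(pred, truth))` over responsible pairs. Each pair
#' contributes a value in `[0, 2)`: 0 iff the boxes coincide, approaching 2
#' as they separate indefinitely. Unlike the Euclidean loss it is invariant
#' to joint rescaling and translation of each pair.
#'
#' @inheritParams euclidean_position_loss
#' @return Non-negative scalar.
#' @export
giou_position_loss <- function(pred, truth) {
  p <- as_box_matrix(pred); t <- as_box_matrix(truth)
  if (nrow(p) != nrow(t)) {
    stop("alignment error: pred and truth lists differ in length", call. = FALSE)
  }
  if (nrow(p) == 0L) return(0)
  sum(1 - box_giou(p, t)$giou)
}

# numerically safe binary cross-entropy with logits and its gradient
bce_logits <- function(x, y) {
  pmax(x, 0) - x * y + log1p(exp(-abs(x)))
}

#' Total detector training loss
#'
#' Combines three terms over one image's raw prediction tensors: a position
#' term over responsible slots (selected by `mode`), a confidence term
#' (binary cross-entropy of objectness over all non-ignored slots), and a
#' classification term (per-class binary cross-entropy over responsible
#' slots). Term weights default to 1.
#'
#' @param target An `fy_target` from [encode_targets()].
#' @param raw Named list of per-scale raw arrays (see [decode_raw()]).
#' @param spec,anchors Matching grid spec and anchors.
#' @param mode Position loss: `"giou"` or `"euclidean"`.
#' @param weights Length-3 numeric `(position, confidence, classification)`.
#' @return A list of class `fy_loss_terms` with fields `position`,
#'   `confidence`, `classification`, `total`.
#' @export
total_loss <- function(target, raw, spec, anchors,
                       mode = c("giou", "euclidean"), weights = c(1, 1, 1)) {
  mode <- match.arg(mode)
  r <- yolo_loss_grad(raw, target, spec, anchors, mode, weights,
                      want_grad = FALSE)
  structure(r$terms, class = "fy_loss_terms")
}

#' @export
print.fy_loss_terms <- function(x, ...) {
  cat(sprintf("loss total %.4f = position %.4f + confidence %.4f + classification %.4f\n",
              x$total, x$position, x$confidence, x$classification))
  invisible(x)
}

# Shared loss + gradient engine for one image. Returns terms and, when
# want_grad, per-scale gradient arrays matching raw. Gradients are of the
# weighted total.
yolo_loss_grad <- function(raw, target, spec, anchors, mode, weights,
                           want_grad = FALSE) {
  pos_l <- conf_l <- cls_l <- 0
  grads <- if (want_grad) vector("list", length(spec$S)) else NULL
  for (si in seq_along(spec$S)) {
    S <- spec$S[si]
    g <- as.character(S)
    a <- raw[[g]]
    tg <- target$t[[g]]
    if (!all(dim(a) == dim(tg))) {
      stop("shape error: raw/target mismatch at scale ", g, call. = FALSE)
    }
    B <- spec$B; C <- spec$C
    dims3 <- c(S, S, B)
    ch <- function(arr, k) array(arr[, , , k], dim = dims3)
    obj_y <- ch(tg, 5)
    ign <- target$ignore[[g]]
    ga <- if (want_grad) array(0, dim = dim(a)) else NULL

    # confidence: all slots except ignored negatives
    o <- ch(a, 5)
    use <- obj_y == 1 | !ign
    conf_l <- conf_l + sum(bce_logits(o, obj_y)[use])
    if (want_grad) {
      gco <- (sigmoid(o) - obj_y) * weights[2]
      gco[!use] <- 0
      ga[, , , 5] <- gco
    }

    idx <- which(obj_y == 1, arr.ind = TRUE)
    if (nrow(idx) > 0L) {
      pw <- anchors$allocation[[g]][, 1] / spec$input_size
      ph <- anchors$allocation[[g]][, 2] / spec$input_size
      # gather responsible slots
      n <- nrow(idx)
      tx <- a[cbind(idx, 1L)]; ty <- a[cbind(idx, 2L)]
      tw <- a[cbind(idx, 3L)]; th <- a[cbind(idx, 4L)]
      sx <- sigmoid(tx); sy <- sigmoid(ty)
      bx <- (idx[, 2] - 1L + sx) / S
      by <- (idx[, 1] - 1L + sy) / S
      # size logits are clamped: beyond |t| = 3 the GIoU surface flattens
      # into a vanishing-gradient plateau, so runaway sizes are cut off
      bw <- pw[idx[, 3]] * exp(clamp(tw, -3, 3))
      bh <- ph[idx[, 3]] * exp(clamp(th, -3, 3))
      in_w <- abs(tw) < 3; in_h <- abs(th) < 3
      pred <- cbind(cx = bx, cy = by, w = bw, h = bh)
      truth <- cbind(cx = tg[cbind(idx, 1L)], cy = tg[cbind(idx, 2L)],
                     w = tg[cbind(idx, 3L)], h = tg[cbind(idx, 4L)])
      if (mode == "giou") {
        pos_l <- pos_l + sum(1 - box_giou(pred, truth)$giou)
        if (want_grad) gbox <- -giou_gradient(pred, truth)
      } else {
        pos_l <- pos_l + euclidean_position_loss(pred, truth)
        if (want_grad) {
          gbox <- cbind(2 * (bx - truth[, 1]), 2 * (by - truth[, 2]),
                        (sqrt(bw) - sqrt(truth[, 3])) / sqrt(bw),
                        (sqrt(bh) - sqrt(truth[, 4])) / sqrt(bh))
        }
      }
      if (want_grad) {
        ga[cbind(idx, 1L)] <- gbox[, 1] * sx * (1 - sx) / S * weights[1]
        ga[cbind(idx, 2L)] <- gbox[, 2] * sy * (1 - sy) / S * weights[1]
        ga[cbind(idx, 3L)] <- gbox[, 3] * bw * in_w * weights[1]
        ga[cbind(idx, 4L)] <- gbox[, 4] * bh * in_h * weights[1]
      }
      # classification over responsible slots
      for (k in seq_len(C)) {
        xk <- a[cbind(idx, 5L + k)]
        yk <- tg[cbind(idx, 5L + k)]
        cls_l <- cls_l + sum(bce_logits(xk, yk))
        if (want_grad) ga[cbind(idx, 5L + k)] <- (sigmoid(xk) - yk) * weights[3]
      }
    }
    if (want_grad) grads[[si]] <- ga
  }
  if (want_grad) names(grads) <- as.character(spec$S)
  total <- weights[1] * pos_l + weights[2] * conf_l + weights[3] * cls_l
  list(terms = list(position = pos_l, confidence = conf_l,
                    classification = cls_l, total = pos_l + conf_l + cls_l),
       weighted_total = total, grads = grads)
}
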