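#' Construct an axis-aligned bounding box
#'
#' Boxes are stored in center form `(cx, cy, w, h)`: horizontal and vertical
#' center, width and height. Coordinates follow the image-array convention
#' (origin top-left, x rightward, y downward) and may be either normalized
#' image fractions in `[0, 1]` (the label-file unit) or pixels; all geometry
#' here is unit-agnostic. Zero- or negative-size boxes are rejected at
#' construction so that downstream union areas are strictly positive.
#'
#' @param cx,cy Box center.
#' @param w,h Box width and height; must be strictly positive.
#' @return A named numeric vector `c(cx, cy, w, h)`.
#' @examples
#' b <- box(0.5, 0.5, 0.2, 0.4)
#' to_corners(b)
#' @export
box <- function(cx, cy, w, h) {
  b <- c(cx = as.numeric(cx), cy = as.numeric(cy),
         w = as.numeric(w), h = as.numeric(h))
  validate_boxes(rbind(b))
  b
}

#' Coerce boxes to an n x 4 matrix in center form
#'
#' Accepts a single box vector, an n x 4 matrix, or a data frame with
#' columns `cx, cy, w, h`.
#'
#' @param x Boxes in any of the accepted forms.
#' @return A numeric matrix with columns `cx, cy, w, h`.
#' @export
as_box_matrix <- function(x) {
  if (is.data.frame(x)) {
    m <- as.matrix(x[, c("cx", "cy", "w", "h")])
  } else if (is.matrix(x)) {
    m <- x[, 1:4, drop = FALSE]
  } else if (is.numeric(x) && length(x) == 4L) {
    m <- matrix(x, nrow = 1L)
  } else {
    stop("cannot interpret input as boxes (need length-4 vector, n x 4 matrix, ",
         "or data frame with cx, cy, w, h)", call. = FALSE)
  }
  storage.mode(m) <- "double"
  colnames(m) <- c("cx", "cy", "w", "h")
  m
}

validate_boxes <- function(m) {
  if (anyNA(m) || any(!is.finite(m))) {
    stop("invalid box: non-finite coordinate", call. = FALSE)
  }
  if (any(m[, 3] <= 0) || any(m[, 4] <= 0)) {
    stop("invalid box: width and height must be strictly positive",
         call. = FALSE)
  }
  invisible(m)
}

#' Convert center-form boxes to corner form
#'
#' @param x Boxes (see [as_box_matrix()]).
#' @return An n x 4 matrix with columns `x1, y1, x2, y2`
#'   (`x1 = cx - w/2`, ..., `y2 = cy + h/2`); a single input box yields a
#'   one-row matrix.
#' @export
to_corners <- function(x) {
  m <- validate_boxes(as_box_matrix(x))
  out <- cbind(x1 = m[, 1] - m[, 3] / 2, y1 = m[, 2] - m[, 4] / 2,
               x2 = m[, 1] + m[, 3] / 2, y2 = m[, 2] + m[, 4] / 2)
  out
}

#' Convert corner-form boxes to center form
#'
#' @param m An n x 4 matrix (or length-4 vector) `x1, y1, x2, y2` with
#'   `x1 < x2`, `y1 < y2`.
#' @return An n x 4 matrix with columns `cx, cy, w, h`.
#' @export
from_corners <- function(m) {
  if (is.numeric(m) && !is.matrix(m)) m <- matrix(m, nrow = 1L)
  out <- cbind(cx = (m[, 1] + m[, 3]) / 2, cy = (m[, 2] + m[, 4]) / 2,
               w = m[, 3] - m[, 1], h = m[, 4] - m[, 2])
  validate_boxes(out)
  out
}

#' Box areas
#' @param x Boxes (see [as_box_matrix()]).
#' @return Numeric vector of areas `w * h`.
#' @export
box_area <- function(x) {
  m <- as_box_matrix(x)
  m[, 3] * m[, 4]
}

# Elementwise overlap decomposition of two equal-length box sets (rows
# recycled if one side has a single row). Returns the raw pieces shared by
# iou / giou / gradient code. Boxes touching along an edge have J = 0 and
# count as disjoint; no epsilon inflation.
overlap_pieces <- function(a, b) {
  ca <- to_corners(a)
  cb <- to_corners(b)
  n <- max(nrow(ca), nrow(cb))
  if (nrow(ca) == 1L && n > 1L) ca <- ca[rep(1L, n), , drop = FALSE]
  if (nrow(cb) == 1L && n > 1L) cb <- cb[rep(1L, n), , drop = FALSE]
  if (nrow(ca) != nrow(cb)) {
    stop("box sets must have equal length (or one of length 1)", call. = FALSE)
  }
  iw <- pmin(ca[, 3], cb[, 3]) - pmax(ca[, 1], cb[, 1])
  ih <- pmin(ca[, 4], cb[, 4]) - pmax(ca[, 2], cb[, 2])
  J <- pmax(iw, 0) * pmax(ih, 0)
  area_a <- (ca[, 3] - ca[, 1]) * (ca[, 4] - ca[, 2])
  area_b <- (cb[, 3] - cb[, 1]) * (cb[, 4] - cb[, 2])
  U <- area_a + area_b - J
  cw <- pmax(ca[, 3], cb[, 3]) - pmin(ca[, 1], cb[, 1])
  ch <- pmax(ca[, 4], cb[, 4]) - pmin(ca[, 2], cb[, 2])
  A <- cw * ch
  list(ca = ca, cb = cb, iw = iw, ih = ih, J = J,
       area_a = area_a, area_b = area_b, U = U, cw = cw, ch = ch, A = A)
}

#' Intersection over union of paired boxes
#'
#' Elementwise IoU `J / U` with `U = area(a) + area(b) - J`. Symmetric,
#' in `[0, 1]`, and 0 for boxes whose interiors are disjoint (including
#' boxes sharing only an edge).
#'
#' @param a,b Boxes (equal-length sets, or one side a single box).
#' @return Numeric vector of IoU values.
#' @export
box_iou <- function(a, b) {
  p <- overlap_pieces(a, b)
  unname(p$J / p$U)
}

#' Generalized IoU decomposition of paired boxes
#'
#' Computes, elementwise, the overlap decomposition underlying the GIoU
#' score: intersection area `J`, union area `U = area(a) + area(b) - J`,
#' smallest-enclosing-box area `A`, `iou = J/U`, and
#' `giou = J/U - (A - U)/A`. GIoU equals IoU exactly when the enclosing
#' box adds no slack (`A = U`), takes its maximum value 1 when the boxes
#' coincide, and tends to -1 as the boxes separate indefinitely.
#'
#' @param a,b Boxes (equal-length sets, or one side a single box).
#' @return A data frame with columns `J, U, A, iou, giou`.
#' @export
box_giou <- function(a, b) {
  p <- overlap_pieces(a, b)
  iou <- p$J / p$U
  data.frame(J = p$J, U = p$U, A = p$A, iou = iou,
             giou = iou - (p$A - p$U) / p$A)
}

#' Gradient of GIoU with respect to the first (predicted) box
#'
#' Analytic subgradient of `giou(pred, truth)` in the center
#' parameterization of `pred`, used by the trainer when backpropagating
#' the GIoU position loss. At ties of the min/max corner selections the
#' one-sided derivative attributing the active corner to the truth box is
#' used (a measure-zero set; any subgradient is valid for SGD).
#'
#' @param pred,truth Boxes (equal-length sets).
#' @return An n x 4 matrix `d giou / d (cx, cy, w, h)` of `pred`.
#' @export
giou_gradient <- function(pred, truth) {
  p <- overlap_pieces(pred, truth)
  ca <- p$ca; cb <- p$cb
  pos <- p$J > 0
  # dJ/d corner of pred: active only where pred supplies the tight corner
  dJ_x1 <- ifelse(pos & (ca[, 1] > cb[, 1]), -p$ih, 0)
  dJ_x2 <- ifelse(pos & (ca[, 3] < cb[, 3]), p$ih, 0)
  dJ_y1 <- ifelse(pos & (ca[, 2] > cb[, 2]), -p$iw, 0)
  dJ_y2 <- ifelse(pos & (ca[, 4] < cb[, 4]), p$iw, 0)
  # d area(pred) / d corner
  w_a <- ca[, 3] - ca[, 1]; h_a <- ca[, 4] - ca[, 2]
  dAr_x1 <- -h_a; dAr_x2 <- h_a; dAr_y1 <- -w_a; dAr_y2 <- w_a
  dU_x1 <- dAr_x1 - dJ_x1; dU_x2 <- dAr_x2 - dJ_x2
  dU_y1 <- dAr_y1 - dJ_y1; dU_y2 <- dAr_y2 - dJ_y2
  # d A (enclosure) / d corner: active where pred supplies the outer corner
  dA_x1 <- ifelse(ca[, 1] < cb[, 1], -p$ch, 0)
  dA_x2 <- ifelse(ca[, 3] > cb[, 3], p$ch, 0)
  dA_y1 <- ifelse(ca[, 2] < cb[, 2], -p$cw, 0)
  dA_y2 <- ifelse(ca[, 4] > cb[, 4], p$cw, 0)
  # giou = J/U - 1 + U/A
  gf <- function(dJ, dU, dA) {
    (dJ * p$U - p$J * dU) / p$U^2 + (dU * p$A - p$U * dA) / p$A^2
  }
  g_x1 <- gf(dJ_x1, dU_x1, dA_x1); g_x2 <- gf(dJ_x2, dU_x2, dA_x2)
  g_y1 <- gf(dJ_y1, dU_y1, dA_y1); g_y2 <- gf(dJ_y2, dU_y2, dA_y2)
  cbind(cx = g_x1 + g_x2, cy = g_y1 + g_y2,
        w = (g_x2 - g_x1) / 2, h = (g_y2 - g_y1) / 2)
}

#' Cross IoU matrix between two box sets
#'
#' @param a An n x 4 box set.
#' @param b An m x 4 box set.
#' @return An n x m matrix of pairwise IoU values.
#' @export
box_iou_cross <- function(a, b) {
  ca <- to_corners(a)
  cb <- to_corners(b)
  iw <- outer(ca[, 3], cb[, 3], pmin) - outer(ca[, 1], cb[, 1], pmax)
  ih <- outer(ca[, 4], cb[, 4], pmin) - outer(ca[, 2], cb[, 2], pmax)
  J <- pmax(iw, 0) * pmax(ih, 0)
  area_a <- (ca[, 3] - ca[, 1]) * (ca[, 4] - ca[, 2])
  area_b <- (cb[, 3] - cb[, 1]) * (cb[, 4] - cb[, 2])
  J / (outer(area_a, area_b, `+`) - J)
}
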