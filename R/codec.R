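#' Grid specification for the multi-scale prediction head
#'
#' Describes the prediction tensor layout: at each of three strides
#' (32, 16, 8 by default) the network predicts an `S x S x B x (4 + 1 + C)`
#' tensor, where `S = input_size / stride`, `B` priors per cell carry 4 box
#' parameters, 1 objectness score and `C` class scores.
#'
#' @param input_size Network input side in pixels; must be divisible by
#'   every stride.
#' @param strides Downsampling factors of the prediction scales.
#' @param B Priors per cell.
#' @param C Number of classes (2: class 0 = red fruit, 1 = green fruit).
#' @return An object of class `fy_gridspec` with fields `input_size`,
#'   `strides`, `S` (grid sizes, coarsest first), `B`, `C`.
#' @examples
#' spec <- grid_spec(416)
#' n_predictions(spec)  # 10647
#' @export
grid_spec <- function(input_size = 416L, strides = c(32L, 16L, 8L),
                      B = 3L, C = 2L) {
  input_size <- as.integer(input_size)
  if (any(input_size %% strides != 0L)) {
    stop(sprintf("config error: input_size %d not divisible by strides %s",
                 input_size, paste(strides, collapse = "/")), call. = FALSE)
  }
  strides <- sort(as.integer(strides), decreasing = TRUE)
  structure(list(input_size = input_size, strides = strides,
                 S = input_size %/% strides, B = as.integer(B),
                 C = as.integer(C)),
            class = "fy_gridspec")
}

#' Total number of predictions emitted per image
#'
#' `sum(S^2 * B)` over the scales; 10,647 for the canonical 416-pixel
#' three-scale spec with 3 priors per cell.
#'
#' @param spec An `fy_gridspec`.
#' @return Integer count.
#' @export
n_predictions <- function(spec) {
  as.integer(sum(spec$S^2 * spec$B))
}

#' Grid cell responsible for an object
#'
#' The cell containing the object's center is responsible for detecting it.
#' Returns 0-based `(row, col)` = `(floor(cy * S), floor(cx * S))`, clamped
#' to the grid so that centers lying exactly on the far image border fall in
#' the last cell.
#'
#' @param cx,cy Normalized box center in `[0, 1]`.
#' @param S Grid size (cells per side).
#' @return Integer vector (or 2-column matrix for vector input) of 0-based
#'   `(row, col)`.
#' @export
responsible_cell <- function(cx, cy, S) {
  if (any(cx < 0 | cx > 1 | cy < 0 | cy > 1)) {
    stop("invalid label: box center outside [0, 1]", call. = FALSE)
  }
  row <- pmin(floor(cy * S), S - 1L)
  col <- pmin(floor(cx * S), S - 1L)
  if (length(cx) == 1L) c(row = as.integer(row), col = as.integer(col))
  else cbind(row = as.integer(row), col = as.integer(col))
}

#' Best-matching prior for a box
#'
#' Selects the (scale, prior) whose co-centered IoU with the box is maximal
#' over all priors. Ties are broken in favor of the smaller-area prior, then
#' the lower prior index.
#'
#' @param b A box (normalized units).
#' @param anchors An `fy_anchors` allocation.
#' @param input_size Network input side in pixels (anchor sizes are stored
#'   in input-frame pixels).
#' @return A list with `grid` (grid size of the matched scale), `prior`
#'   (1-based index within the scale), and `iou`.
#' @export
match_prior <- function(b, anchors, input_size) {
  m <- as_box_matrix(b)
  flat <- anchor_table(anchors)
  ious <- cocentered_iou(m[, 3:4, drop = FALSE] * input_size,
                         flat[, c("w", "h"), drop = FALSE])[1L, ]
  area <- flat[, "w"] * flat[, "h"]
  best <- order(-round(ious, 12), area, seq_along(ious))[1L]
  list(grid = as.integer(flat[best, "grid"]),
       prior = as.integer(flat[best, "prior"]), iou = ious[best])
}

# 9 x 4 matrix: grid, prior, w, h
anchor_table <- function(anchors) {
  do.call(rbind, lapply(as.character(anchors$grid_sizes), function(g) {
    a <- anchors$allocation[[g]]
    cbind(grid = as.numeric(g), prior = seq_len(nrow(a)),
          w = a[, 1], h = a[, 2])
  }))
}

empty_target <- function(spec) {
  tgt <- lapply(spec$S, function(S) {
    array(0, dim = c(S, S, spec$B, 5L + spec$C))
  })
  names(tgt) <- as.character(spec$S)
  tgt
}

#' Encode ground-truth labels into per-scale grid targets
#'
#' For each labeled object the responsible cell at the scale of its
#' best-matching prior receives objectness 1, the class one-hot, and the
#' normalized box `(cx, cy, w, h)`; every other slot is zero. When two
#' objects claim the same (cell, prior) slot the larger-area object wins and
#' the collision is counted. Priors other than the best whose co-centered
#' IoU with some object exceeds `ignore_iou` are marked in the ignore mask
#' and are excluded from the no-object confidence loss.
#'
#' @param labels A data frame with columns `class` (0-based, `< C`),
#'   `cx, cy, w, h` (normalized).
#' @param spec An `fy_gridspec`.
#' @param anchors An `fy_anchors` whose grids match `spec$S`.
#' @param ignore_iou Co-centered IoU above which a non-best prior at the
#'   responsible cell is ignored by the confidence loss.
#' @return A list of class `fy_target`: `t` — per-scale arrays
#'   `S x S x B x (5 + C)` with channels `(cx, cy, w, h, obj, class...)`,
#'   `ignore` — per-scale logical arrays `S x S x B`, `collisions` — count
#'   of overwritten slots, `n_objects`.
#' @export
encode_targets <- function(labels, spec, anchors, ignore_iou = 0.5) {
  labels <- normalize_labels(labels, spec$C)
  tgt <- empty_target(spec)
  ign <- lapply(spec$S, function(S) array(FALSE, dim = c(S, S, spec$B)))
  names(ign) <- as.character(spec$S)
  collisions <- 0L
  if (nrow(labels) > 0L) {
    flat <- anchor_table(anchors)
    # ascending area: on a slot collision the later (larger) write wins
    ord <- order(labels$w * labels$h)
    for (i in ord) {
      lb <- labels[i, ]
      mp <- match_prior(c(lb$cx, lb$cy, lb$w, lb$h), anchors, spec$input_size)
      g <- as.character(mp$grid)
      S <- as.integer(mp$grid)
      cell <- responsible_cell(lb$cx, lb$cy, S)
      slot <- tgt[[g]][cell["row"] + 1L, cell["col"] + 1L, mp$prior, ]
      if (slot[5L] == 1) collisions <- collisions + 1L
      vec <- c(lb$cx, lb$cy, lb$w, lb$h, 1, rep(0, spec$C))
      vec[5L + 1L + lb$class] <- 1
      tgt[[g]][cell["row"] + 1L, cell["col"] + 1L, mp$prior, ] <- vec
      # ignore mask: non-best priors with high co-centered IoU, at the
      # object's responsible cell on each scale
      ious <- cocentered_iou(cbind(lb$w, lb$h) * spec$input_size,
                             flat[, c("w", "h"), drop = FALSE])[1L, ]
      high <- which(ious > ignore_iou)
      for (j in high) {
        gj <- as.character(flat[j, "grid"])
        Sj <- as.integer(flat[j, "grid"])
        if (gj == g && flat[j, "prior"] == mp$prior) next
        cj <- responsible_cell(lb$cx, lb$cy, Sj)
        ign[[gj]][cj["row"] + 1L, cj["col"] + 1L, flat[j, "prior"]] <- TRUE
      }
    }
  }
  structure(list(t = tgt, ignore = ign, collisions = collisions,
                 n_objects = nrow(labels)),
            class = "fy_target")
}

normalize_labels <- function(labels, C) {
  if (is.null(labels) || nrow(labels) == 0L) {
    return(data.frame(class = integer(0), cx = numeric(0), cy = numeric(0),
                      w = numeric(0), h = numeric(0)))
  }
  labels <- as.data.frame(labels)[, c("class", "cx", "cy", "w", "h")]
  if (any(labels$class < 0L | labels$class >= C)) {
    stop(sprintf("invalid label: class index outside [0, %d]", C - 1L),
         call. = FALSE)
  }
  validate_boxes(as_box_matrix(labels))
  if (any(labels$cx < 0 | labels$cx > 1 | labels$cy < 0 | labels$cy > 1)) {
    stop("invalid label: center outside [0, 1]", call. = FALSE)
  }
  labels
}

#' Decode raw network outputs into candidate detections
#'
#' Applies the standard YOLOv3 parameterization: box center
#' `(cell + sigmoid(tx, ty)) / S`, box size
#' `anchor * exp(tw, th) / input_size`, confidence
#' `sigmoid(objectness) * max_c sigmoid(class_c)`, class by argmax. One
#' candidate is emitted per (cell, prior) slot — `n_predictions(spec)` in
#' total.
#'
#' @param raw A named list of per-scale arrays `S x S x B x (5 + C)` with
#'   channels `(tx, ty, tw, th, obj, class...)`; names are grid sizes.
#' @param spec An `fy_gridspec`.
#' @param anchors An `fy_anchors`.
#' @return A data frame with columns `class, cx, cy, w, h, confidence`
#'   (normalized units) plus bookkeeping columns `grid, row, col, prior`.
#' @export
decode_raw <- function(raw, spec, anchors) {
  out <- lapply(seq_along(spec$S), function(si) {
    S <- spec$S[si]
    g <- as.character(S)
    a <- raw[[g]]
    if (is.null(a)) stop("shape error: missing scale ", g, call. = FALSE)
    if (!all(dim(a) == c(S, S, spec$B, 5L + spec$C))) {
      stop(sprintf("shape error: scale %s has dim (%s), expected (%d,%d,%d,%d)",
                   g, paste(dim(a), collapse = ","), S, S, spec$B,
                   5L + spec$C), call. = FALSE)
    }
    pw <- anchors$allocation[[g]][, 1] / spec$input_size
    ph <- anchors$allocation[[g]][, 2] / spec$input_size
    # index grids: dim order (row, col, prior)
    ch <- function(k) array(a[, , , k], dim = c(S, S, spec$B))
    rows <- array(rep(0:(S - 1L), times = S * spec$B), dim = c(S, S, spec$B))
    cols <- array(rep(rep(0:(S - 1L), each = S), times = spec$B),
                  dim = c(S, S, spec$B))
    priors <- array(rep(seq_len(spec$B), each = S * S), dim = c(S, S, spec$B))
    cx <- (cols + sigmoid(ch(1))) / S
    cy <- (rows + sigmoid(ch(2))) / S
    w <- pw[priors] * exp(clamp(ch(3), -8, 8))  # overflow guard
    h <- ph[priors] * exp(clamp(ch(4), -8, 8))
    pobj <- sigmoid(ch(5))
    cls <- sigmoid(array(a[, , , 5L + seq_len(spec$C)],
                         dim = c(S, S, spec$B, spec$C)))
    dim(cls) <- c(S * S * spec$B, spec$C)
    best <- max.col(cls, ties.method = "first")
    conf <- as.vector(pobj) * cls[cbind(seq_len(nrow(cls)), best)]
    data.frame(class = best - 1L, cx = as.vector(cx), cy = as.vector(cy),
               w = as.vector(w), h = as.vector(h), confidence = conf,
               grid = S, row = as.vector(rows), col = as.vector(cols),
               prior = as.vector(priors))
  })
  do.call(rbind, out)
}

#' Represent an encoded target as a raw prediction tensor
#'
#' Inverts the decode transform for the responsible slots (logit of the cell
#' offset, log of the anchor ratio) and saturates the objectness and class
#' logits, producing the raw tensor an ideal network would emit for those
#' labels. Non-responsible slots get strongly negative objectness. Used for
#' round-trip testing and loss limit checks.
#'
#' @param target An `fy_target`.
#' @param spec,anchors Matching grid spec and anchors.
#' @param sat Saturation magnitude for objectness/class logits.
#' @return A named list of per-scale raw arrays.
#' @export
target_to_raw <- function(target, spec, anchors, sat = 12) {
  raw <- lapply(seq_along(spec$S), function(si) {
    S <- spec$S[si]
    g <- as.character(S)
    tg <- target$t[[g]]
    a <- array(0, dim = dim(tg))
    a[, , , 5] <- -sat
    obj <- which(array(tg[, , , 5], dim = dim(tg)[1:3]) == 1, arr.ind = TRUE)
    if (nrow(obj) > 0L) {
      pw <- anchors$allocation[[g]][, 1] / spec$input_size
      ph <- anchors$allocation[[g]][, 2] / spec$input_size
      for (r in seq_len(nrow(obj))) {
        i <- obj[r, 1]; j <- obj[r, 2]; b <- obj[r, 3]
        v <- tg[i, j, b, ]
        tx <- stats::qlogis(clamp(v[1] * S - (j - 1L), 1e-7, 1 - 1e-7))
        ty <- stats::qlogis(clamp(v[2] * S - (i - 1L), 1e-7, 1 - 1e-7))
        a[i, j, b, 1:4] <- c(tx, ty, log(v[3] / pw[b]), log(v[4] / ph[b]))
        a[i, j, b, 5] <- sat
        a[i, j, b, 5L + seq_len(spec$C)] <- ifelse(
          v[5L + seq_len(spec$C)] == 1, sat, -sat)
      }
    }
    a
  })
  names(raw) <- as.character(spec$S)
  raw
}

sigmoid <- function(x) 1 / (1 + exp(-x))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Read / write YOLO-format plain-text labels
#'
#' One line per object: `class cx cy w h`, floats normalized to `[0, 1]`,
#' class 0 = red (mature) fruit, 1 = green (immature) fruit.
#'
#' @param path Label file path; a missing or empty file reads as zero rows.
#' @return A data frame with columns `class, cx, cy, w, h`.
#' @export
read_yolo_labels <- function(path) {
  if (!file.exists(path) || file.size(path) == 0L) {
    return(normalize_labels(NULL, 2L))
  }
  m <- as.matrix(utils::read.table(path, col.names = c("class", "cx", "cy", "w", "h")))
  data.frame(class = as.integer(m[, 1]), cx = m[, 2], cy = m[, 3],
             w = m[, 4], h = m[, 5])
}

#' @rdname read_yolo_labels
#' @param labels Data frame with columns `class, cx, cy, w, h`.
#' @export
write_yolo_labels <- function(labels, path) {
  if (nrow(labels) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- sprintf("%d %.6f %.6f %.6f %.6f", as.integer(labels$class),
                   labels$cx, labels$cy, labels$w, labels$h)
  writeLines(lines, path)
  invisible(path)
}
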