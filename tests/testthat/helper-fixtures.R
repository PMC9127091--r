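# shared fixtures, built in code

# the nine printed prior sizes of the reference three-scale allocation
table1_sizes <- function() {
  rbind(c(73, 46), c(93, 75), c(128, 125),
        c(36, 45), c(52, 34), c(55, 64),
        c(22, 17), c(25, 31), c(37, 24))
}

# a well-spread synthetic anchor set for a given input size
toy_anchors <- function(input_size = 416L) {
  s <- input_size / 416
  sizes <- cbind(w = c(12, 25, 20, 55, 40, 90, 70, 150, 120) * s,
                 h = c(16, 18, 40, 30, 70, 45, 100, 80, 160) * s)
  allocate_to_scales(sizes, grid_spec(as.integer(input_size))$S)
}

random_boxes <- function(n, center_range = c(0, 1), size_range = c(0.05, 0.5)) {
  cbind(cx = stats::runif(n, center_range[1], center_range[2]),
        cy = stats::runif(n, center_range[1], center_range[2]),
        w = stats::runif(n, size_range[1], size_range[2]),
        h = stats::runif(n, size_range[1], size_range[2]))
}

random_labels <- function(n, C = 2L) {
  data.frame(class = sample(0:(C - 1L), n, replace = TRUE),
             cx = stats::runif(n, 0.08, 0.92), cy = stats::runif(n, 0.08, 0.92),
             w = stats::runif(n, 0.03, 0.25), h = stats::runif(n, 0.03, 0.25))
}

# lattice-rasterization oracle for IoU/GIoU: counts 512 x 512 sample points
# over the enclosing region of the pair; membership is tested pointwise
rasterized_giou <- function(a, b, n_lattice = 512L) {
  ca <- to_corners(a)[1, ]
  cb <- to_corners(b)[1, ]
  ex <- range(c(ca[c(1, 3)], cb[c(1, 3)]))
  ey <- range(c(ca[c(2, 4)], cb[c(2, 4)]))
  # cell-centered lattice over the enclosing box
  xs <- seq(ex[1], ex[2], length.out = n_lattice + 1L)
  xs <- (xs[-1] + xs[-length(xs)]) / 2
  ys <- seq(ey[1], ey[2], length.out = n_lattice + 1L)
  ys <- (ys[-1] + ys[-length(ys)]) / 2
  in_a_x <- xs >= ca[1] & xs <= ca[3]; in_a_y <- ys >= ca[2] & ys <= ca[4]
  in_b_x <- xs >= cb[1] & xs <= cb[3]; in_b_y <- ys >= cb[2] & ys <= cb[4]
  cell <- (diff(ex) / n_lattice) * (diff(ey) / n_lattice)
  n_a <- sum(in_a_x) * sum(in_a_y)
  n_b <- sum(in_b_x) * sum(in_b_y)
  n_i <- sum(in_a_x & in_b_x) * sum(in_a_y & in_b_y)
  J <- n_i * cell
  U <- (n_a + n_b - n_i) * cell
  A <- diff(ex) * diff(ey)
  list(iou = J / U, giou = J / U - (A - U) / A)
}

# plain O(n^2) reference NMS: literal definition, per class
reference_nms <- function(cands, iou_threshold) {
  kept <- NULL
  for (cl in sort(unique(cands$class))) {
    d <- cands[cands$class == cl, , drop = FALSE]
    d <- d[order(-d$confidence, -(d$w * d$h), seq_len(nrow(d))), , drop = FALSE]
    chosen <- logical(nrow(d))
    for (i in seq_len(nrow(d))) {
      suppressed <- FALSE
      for (j in which(chosen)) {
        if (box_iou(as_box_matrix(d[i, ]), as_box_matrix(d[j, ])) > iou_threshold) {
          suppressed <- TRUE
          break
        }
      }
      if (!suppressed) chosen[i] <- TRUE
    }
    kept <- rbind(kept, d[chosen, , drop = FALSE])
  }
  rownames(kept) <- NULL
  kept
}

random_detections <- function(n, C = 2L) {
  data.frame(class = sample(0:(C - 1L), n, replace = TRUE),
             cx = stats::runif(n, 0.2, 0.8), cy = stats::runif(n, 0.2, 0.8),
             w = stats::runif(n, 0.05, 0.4), h = stats::runif(n, 0.05, 0.4),
             confidence = stats::runif(n))
}
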