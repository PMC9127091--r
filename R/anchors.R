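#' Co-centered IoU between (width, height) pairs
#'
#' IoU of two rectangles placed with coincident centers, so only the sizes
#' matter: `min(w1,w2) * min(h1,h2) / (w1*h1 + w2*h2 - overlap)`. This is
#' the similarity underlying the 1-IoU clustering distance used for prior
#' estimation, where box position is irrelevant.
#'
#' @param wh1 An n x 2 matrix of (width, height) pairs.
#' @param wh2 An m x 2 matrix of (width, height) pairs.
#' @return An n x m matrix of IoU values in `(0, 1]`.
#' @export
cocentered_iou <- function(wh1, wh2) {
  wh1 <- size_matrix(wh1)
  wh2 <- size_matrix(wh2)
  ow <- outer(wh1[, 1], wh2[, 1], pmin)
  oh <- outer(wh1[, 2], wh2[, 2], pmin)
  J <- ow * oh
  J / (outer(wh1[, 1] * wh1[, 2], wh2[, 1] * wh2[, 2], `+`) - J)
}

size_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, ncol = 2L, byrow = TRUE)
  m <- x[, 1:2, drop = FALSE]
  storage.mode(m) <- "double"
  if (any(m <= 0) || anyNA(m)) {
    stop("invalid box sizes: widths and heights must be positive", call. = FALSE)
  }
  colnames(m) <- c("w", "h")
  m
}

#' Estimate prior-box sizes by K-means under the 1-IoU distance
#'
#' Clusters annotated (width, height) pairs with Lloyd-type iterations where
#' the distance between a box size and a centroid is `1 - IoU` of the two
#' rectangles co-centered at the origin, and centroids are updated as the
#' per-cluster arithmetic mean width and height. Initialization is
#' k-means++-style seeding on the same distance; the best of `restarts`
#' seedings by total within-cluster distance is returned. Iteration stops at
#' the assignment fixpoint, or as soon as an update step fails to decrease
#' the total distance (the mean update is a heuristic for the IoU objective,
#' so the last non-improving step is discarded), or after `max_iter` rounds.
#'
#' @param box_sizes An n x 2 matrix (or data frame / flat vector) of box
#'   (width, height) pairs, typically in pixels of the network input frame.
#' @param k Number of priors to estimate (9 for the three-scale detector).
#' @param seed Integer seed for the random initializations.
#' @param restarts Number of random initializations to try.
#' @param max_iter Maximum Lloyd iterations per restart.
#' @return A list of class `fy_kmeans` with elements `sizes` (k x 2 matrix
#'   sorted by area ascending), `tot_dist` (total within-cluster 1-IoU
#'   distance), `trace` (per-iteration total distance of the winning
#'   restart; non-increasing), and `assignment`.
#' @export
kmeans_anchors <- function(box_sizes, k = 9L, seed = 17L, restarts = 10L,
                           max_iter = 300L) {
  wh <- size_matrix(box_sizes)
  if (nrow(wh) == 0L) stop("empty input: no box sizes to cluster", call. = FALSE)
  if (k < 1L) stop("k must be at least 1", call. = FALSE)
  n_distinct <- nrow(unique(wh))
  if (n_distinct < k) {
    stop(sprintf("infeasible clustering: %d distinct sizes < k = %d",
                 n_distinct, k), call. = FALSE)
  }
  best <- NULL
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))
  for (r in seq_len(max(1L, restarts))) {
    fit <- kmeans_iou_once(wh, k, max_iter)
    if (is.null(best) || fit$tot_dist < best$tot_dist) best <- fit
  }
  ord <- order(best$centers[, 1] * best$centers[, 2], best$centers[, 1])
  sizes <- best$centers[ord, , drop = FALSE]
  colnames(sizes) <- c("w", "h")
  structure(list(sizes = sizes, tot_dist = best$tot_dist,
                 trace = best$trace,
                 assignment = match(best$assignment, ord)),
            class = "fy_kmeans")
}

# one k-means++ seeding + Lloyd loop under the 1-IoU distance
kmeans_iou_once <- function(wh, k, max_iter) {
  n <- nrow(wh)
  # k-means++ seeding: first center uniform, then proportional to distance
  centers <- wh[sample.int(n, 1L), , drop = FALSE]
  while (nrow(centers) < k) {
    d <- apply(1 - cocentered_iou(wh, centers), 1L, min)
    if (sum(d) <= 0) {
      # all points coincide with some center; pick any new distinct row
      cand <- which(!duplicated(rbind(centers, wh))[-seq_len(nrow(centers))])
      centers <- rbind(centers, wh[cand[1L], ])
      next
    }
    centers <- rbind(centers, wh[sample.int(n, 1L, prob = d), ])
  }
  assign_prev <- rep(0L, n)
  trace <- numeric(0)
  tot_prev <- Inf
  centers_prev <- centers
  for (it in seq_len(max_iter)) {
    d <- 1 - cocentered_iou(wh, centers)
    assignment <- max.col(-d, ties.method = "first")
    # empty clusters: seize the farthest member of the largest cluster
    for (j in which(tabulate(assignment, k) == 0L)) {
      big <- which.max(tabulate(assignment, k))
      members <- which(assignment == big)
      far <- members[which.max(d[cbind(members, big)])]
      assignment[far] <- j
    }
    tot <- sum(d[cbind(seq_len(n), assignment)])
    if (tot > tot_prev + 1e-12) break  # mean update worsened the objective
    trace <- c(trace, tot)
    converged <- identical(assignment, assign_prev)
    centers_prev <- centers
    assign_prev <- assignment
    tot_prev <- tot
    if (converged) break
    centers <- do.call(rbind, lapply(seq_len(k), function(j) {
      colMeans(wh[assignment == j, , drop = FALSE])
    }))
  }
  list(centers = centers_prev, assignment = assign_prev,
       tot_dist = tot_prev, trace = trace)
}

#' Allocate nine prior sizes to the three grid scales
#'
#' Sorts the priors by area and assigns the three largest to the coarsest
#' grid (smallest cell count, largest receptive field), the middle three to
#' the middle grid, and the three smallest to the finest grid, mirroring the
#' conventional allocation of a 13/26/52 three-scale head.
#'
#' @param sizes A 9 x 2 matrix of (width, height) prior sizes in input-frame
#'   pixels.
#' @param grid_sizes Three grid sizes (cells per side), e.g. `c(13, 26, 52)`.
#' @return An object of class `fy_anchors`: list with `sizes` (9 x 2,
#'   area-ascending), `grid_sizes` (ascending), and `allocation`, a list
#'   keyed by grid size, each a 3 x 2 matrix area-ascending.
#' @export
allocate_to_scales <- function(sizes, grid_sizes = c(13L, 26L, 52L)) {
  sizes <- size_matrix(sizes)
  if (nrow(sizes) != 9L) {
    stop(sprintf("shape error: need exactly 9 prior sizes, got %d", nrow(sizes)),
         call. = FALSE)
  }
  if (length(grid_sizes) != 3L) {
    stop("shape error: need exactly 3 grid sizes", call. = FALSE)
  }
  grid_sizes <- sort(as.integer(grid_sizes))
  ord <- order(sizes[, 1] * sizes[, 2], seq_len(9L))  # stable under ties
  sizes <- sizes[ord, , drop = FALSE]
  allocation <- list()
  # coarsest grid (fewest cells) takes the largest-area third
  thirds <- list(7:9, 4:6, 1:3)
  for (i in 1:3) {
    allocation[[as.character(grid_sizes[i])]] <-
      sizes[thirds[[i]], , drop = FALSE]
  }
  structure(list(sizes = sizes, grid_sizes = grid_sizes,
                 allocation = allocation),
            class = "fy_anchors")
}

#' @export
print.fy_anchors <- function(x, ...) {
  cat("Prior boxes (", nrow(x$sizes), " sizes, input-frame pixels)\n", sep = "")
  for (g in rev(as.character(x$grid_sizes))) {
    a <- x$allocation[[g]]
    cat(sprintf("  grid %3s x %-3s: %s\n", g, g,
                paste(sprintf("(%.0f x %.0f)", a[, 1], a[, 2]), collapse = " ")))
  }
  invisible(x)
}

#' Write / read an anchor set as plain-text YAML
#'
#' The file maps each grid size to three `w h` strings, e.g.
#' `"13": ["73 46", "93 75", "128 125"]`.
#'
#' @param anchors An `fy_anchors` object.
#' @param path Output path.
#' @export
write_anchors <- function(anchors, path) {
  stopifnot(inherits(anchors, "fy_anchors"))
  out <- lapply(anchors$allocation, function(a) {
    apply(a, 1L, function(r) paste(format(r, trim = TRUE), collapse = " "))
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_anchors
#' @return `read_anchors()` returns the `fy_anchors` object.
#' @export
read_anchors <- function(path) {
  raw <- yaml::read_yaml(path)
  grids <- sort(as.integer(names(raw)))
  sizes <- do.call(rbind, lapply(raw, function(rows) {
    do.call(rbind, lapply(rows, function(s) as.numeric(strsplit(s, "\\s+")[[1]])))
  }))
  allocate_to_scales(sizes, grids)
}
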