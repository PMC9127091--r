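# Synthetic plant-factory scenes: red (mature) and green (immature) fruit
# rendered as shaded ellipses over textured green foliage, in sparse, dense
# and leaf-occluded viewing regimes, with YOLO-format labels. The generator
# replaces unavailable real imagery; its color model keeps red vs green
# trivially separable while green fruit remains deliberately close to the
# foliage (the hard confusion in real scenes).

#' Scene generation configuration
#'
#' @param image_size Image side in pixels.
#' @param n_red,n_green Fruit counts per class.
#' @param regime `"sparse"` (pairwise box IoU 0), `"dense"` (clustered,
#'   pairwise IoU up to 0.4) or `"occluded"` (each fruit partly covered by
#'   a foreground leaf).
#' @param fruit_radius_range Semi-axis interval in pixels; default
#'   5--10% of the image side.
#' @param occluder_fraction Minimum fraction of each occluded fruit's area
#'   covered by its leaf (default 0.4).
#' @param seed Integer seed; scenes are byte-reproducible under it.
#' @return A list of class `fy_scene_config`.
#' @export
scene_config <- function(image_size = 416L, n_red = 4L, n_green = 4L,
                         regime = c("sparse", "dense", "occluded"),
                         fruit_radius_range = NULL,
                         occluder_fraction = 0.4, seed = 1L) {
  regime <- match.arg(regime)
  if (is.null(fruit_radius_range)) {
    fruit_radius_range <- c(0.05, 0.10) * image_size
  }
  stopifnot(n_red >= 0, n_green >= 0,
            fruit_radius_range[2] < image_size / 2)
  structure(list(image_size = as.integer(image_size),
                 n_red = as.integer(n_red), n_green = as.integer(n_green),
                 regime = regime, fruit_radius_range = fruit_radius_range,
                 occluder_fraction = occluder_fraction,
                 seed = as.integer(seed)),
            class = "fy_scene_config")
}

hsv_rgb <- function(h, s, v) {
  as.vector(grDevices::col2rgb(grDevices::hsv(h %% 1, clamp(s, 0, 1),
                                              clamp(v, 0, 1)))) / 255
}

# draw a shaded axis-aligned ellipse; pixel coords, row = y, col = x
draw_ellipse <- function(img, cx, cy, a, b, rgb_base, shade = 0.5) {
  H <- dim(img)[1]; W <- dim(img)[2]
  ys <- max(1L, floor(cy - b)):min(H, ceiling(cy + b))
  xs <- max(1L, floor(cx - a)):min(W, ceiling(cx + a))
  if (length(ys) == 0L || length(xs) == 0L) return(img)
  r2 <- outer(((ys - cy) / b)^2, ((xs - cx) / a)^2, `+`)
  mask <- r2 <= 1
  if (!any(mask)) return(img)
  light <- clamp(1.15 - shade * r2, 0.2, 1.3)
  for (k in 1:3) {
    plane <- img[ys, xs, k]
    plane[mask] <- clamp(rgb_base[k] * light[mask], 0, 1)
    img[ys, xs, k] <- plane
  }
  img
}

ellipse_mask <- function(H, W, cx, cy, a, b) {
  outer(((seq_len(H) - cy) / b)^2, ((seq_len(W) - cx) / a)^2, `+`) <= 1
}

# smooth value-noise field in [0,1] via bilinear upsampling of coarse noise
noise_field <- function(H, W, cells = 8L) {
  g <- matrix(stats::runif((cells + 1L)^2), cells + 1L)
  fy <- seq(1, cells + 1L, length.out = H)
  fx <- seq(1, cells + 1L, length.out = W)
  i0 <- pmin(floor(fy), cells); j0 <- pmin(floor(fx), cells)
  ty <- fy - i0; tx <- fx - j0
  v00 <- g[i0, j0]; v10 <- g[i0 + 1L, j0]
  v01 <- g[i0, j0 + 1L]; v11 <- g[i0 + 1L, j0 + 1L]
  ty_m <- matrix(ty, H, W); tx_m <- matrix(tx, H, W, byrow = TRUE)
  v00 * (1 - ty_m) * (1 - tx_m) + v10 * ty_m * (1 - tx_m) +
    v01 * (1 - ty_m) * tx_m + v11 * ty_m * tx_m
}

#' Generate one labeled synthetic scene
#'
#' Renders the configured fruit counts over a textured foliage background.
#' Labels are the tight (amodal) bounding boxes of the fruit ellipses,
#' recorded before any occluding leaf is drawn, matching how annotators
#' label partially hidden fruit.
#'
#' @param config A [scene_config()].
#' @return A list of class `fy_scene`: `image` (`H x W x 3` array in
#'   `[0, 1]`), `labels` (YOLO data frame), `regime`, `audit` (per-fruit
#'   box fill fraction and occluder coverage).
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "fy_scene_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)
  N <- config$image_size
  # foliage background: hue/value jittered per scene, textured per pixel
  fol_h <- 0.26 + stats::runif(1, -0.03, 0.03)
  fol_s <- 0.55 + stats::runif(1, -0.08, 0.08)
  base_v <- 0.32 + stats::runif(1, -0.04, 0.04)
  tex <- noise_field(N, N, cells = 8L)
  img <- array(0, dim = c(N, N, 3))
  for (k in 1:3) {
    lo <- hsv_rgb(fol_h, fol_s, base_v)
    hi <- hsv_rgb(fol_h, fol_s, base_v + 0.28)
    img[, , k] <- lo[k] + (hi[k] - lo[k]) * tex
  }
  # background leaf clutter
  for (i in seq_len(max(6L, N %/% 24L))) {
    col <- hsv_rgb(fol_h + stats::runif(1, -0.02, 0.02),
                   fol_s + stats::runif(1, -0.1, 0.1),
                   base_v + stats::runif(1, -0.08, 0.22))
    img <- draw_ellipse(img, stats::runif(1, 1, N), stats::runif(1, 1, N),
                        stats::runif(1, 0.04, 0.12) * N,
                        stats::runif(1, 0.02, 0.06) * N, col, shade = 0.25)
  }

  fruits <- place_fruits(config)
  labels <- data.frame(class = integer(0), cx = numeric(0), cy = numeric(0),
                       w = numeric(0), h = numeric(0))
  audit <- data.frame(class = integer(0), box_fill = numeric(0),
                      occluded_fraction = numeric(0))
  for (i in seq_len(nrow(fruits))) {
    f <- fruits[i, ]
    if (f$class == 0L) {
      col <- hsv_rgb(stats::runif(1, -0.02, 0.02), 0.85 + stats::runif(1, -0.08, 0.08),
                     0.55 + stats::runif(1, -0.06, 0.06))
    } else {
      col <- hsv_rgb(0.30 + stats::runif(1, -0.015, 0.015),
                     0.65 + stats::runif(1, -0.06, 0.06),
                     0.42 + stats::runif(1, -0.04, 0.04))
    }
    img <- draw_ellipse(img, f$cx, f$cy, f$a, f$b, col, shade = 0.55)
    labels <- rbind(labels, data.frame(class = f$class, cx = f$cx / N,
                                       cy = f$cy / N, w = 2 * f$a / N,
                                       h = 2 * f$b / N))
    # discrete box fill: ellipse pixels over box pixels
    box_px <- (2 * ceiling(f$a)) * (2 * ceiling(f$b))
    fill <- sum(ellipse_mask(N, N, f$cx, f$cy, f$a, f$b)) / box_px
    audit <- rbind(audit, data.frame(class = f$class, box_fill = fill,
                                     occluded_fraction = 0))
  }
  if (config$regime == "occluded" && nrow(fruits) > 0L) {
    for (i in seq_len(nrow(fruits))) {
      f <- fruits[i, ]
      r <- draw_occluder(img, f, config, fol_h, fol_s, base_v, N)
      img <- r$img
      audit$occluded_fraction[i] <- r$coverage
    }
  }
  structure(list(image = img, labels = labels, regime = config$regime,
                 audit = audit), class = "fy_scene")
}

# sample fruit centers and semi-axes per regime; rejection sampling with a
# hard cap, erroring if the configuration cannot be packed
place_fruits <- function(config) {
  N <- config$image_size
  rr <- config$fruit_radius_range
  classes <- c(rep(0L, config$n_red), rep(1L, config$n_green))
  n <- length(classes)
  out <- data.frame(class = integer(0), cx = numeric(0), cy = numeric(0),
                    a = numeric(0), b = numeric(0))
  if (n == 0L) return(out)
  max_iou <- switch(config$regime, sparse = 0, dense = 0.4, occluded = 0)
  clusters <- NULL
  if (config$regime == "dense") {
    k <- max(1L, ceiling(n / 4L))
    clusters <- cbind(stats::runif(k, 0.25 * N, 0.75 * N),
                      stats::runif(k, 0.25 * N, 0.75 * N))
  }
  boxes <- NULL
  tries <- 0L
  for (i in seq_len(n)) {
    repeat {
      tries <- tries + 1L
      if (tries > 10000L) {
        stop("packing error: could not place fruits after 10,000 attempts",
             call. = FALSE)
      }
      a <- stats::runif(1, rr[1], rr[2])
      b <- a * stats::runif(1, 0.8, 1.2)
      b <- min(b, rr[2])
      if (is.null(clusters)) {
        cx <- stats::runif(1, a + 1, N - a - 1)
        cy <- stats::runif(1, b + 1, N - b - 1)
      } else {
        ctr <- clusters[sample.int(nrow(clusters), 1L), ]
        cx <- clamp(ctr[1] + stats::rnorm(1, 0, 1.2 * rr[2]), a + 1, N - a - 1)
        cy <- clamp(ctr[2] + stats::rnorm(1, 0, 1.2 * rr[2]), b + 1, N - b - 1)
      }
      cand <- c(cx, cy, 2 * a, 2 * b)
      ok <- if (is.null(boxes)) TRUE else {
        ious <- box_iou(boxes, matrix(cand, 1))
        if (max_iou == 0) all(ious == 0) else all(ious <= max_iou)
      }
      if (ok) break
    }
    boxes <- rbind(boxes, cand)
    out <- rbind(out, data.frame(class = classes[i], cx = cx, cy = cy,
                                 a = a, b = b))
  }
  out[sample.int(nrow(out)), , drop = FALSE]  # shuffle draw order
}

# draw a foreground leaf over a fruit until the required coverage is met
draw_occluder <- function(img, f, config, fol_h, fol_s, base_v, N) {
  frac <- config$occluder_fraction
  fruit_mask <- ellipse_mask(N, N, f$cx, f$cy, f$a, f$b)
  fruit_px <- sum(fruit_mask)
  la <- f$a * 1.1
  lb <- f$b * 0.9
  ang <- stats::runif(1, 0, 2 * pi)
  # start at the fruit rim and slide the leaf center inwards until covered
  for (step in seq(1, 0, by = -0.1)) {
    lx <- f$cx + cos(ang) * f$a * step
    ly <- f$cy + sin(ang) * f$b * step
    cov <- sum(fruit_mask & ellipse_mask(N, N, lx, ly, la, lb)) / fruit_px
    if (cov >= frac) break
  }
  col <- hsv_rgb(fol_h + stats::runif(1, -0.02, 0.02), fol_s + 0.05,
                 base_v + stats::runif(1, 0.05, 0.2))
  img <- draw_ellipse(img, lx, ly, la, lb, col, shade = 0.2)
  list(img = img, coverage = cov)
}

#' Augment a labeled image
#'
#' Geometric operations transform the labels consistently; blur leaves them
#' unchanged. Supported: `rotate90` (quarter turn,
#' `(cx, cy, w, h) -> (1 - cy, cx, h, w)`), `hflip` (`cx -> 1 - cx`),
#' `vflip` (`cy -> 1 - cy`), `blur` (Gaussian).
#'
#' @param image `H x W x 3` array.
#' @param labels YOLO label data frame.
#' @param op One of `"rotate90", "hflip", "vflip", "blur"`.
#' @param sigma Gaussian sigma for `blur` (pixels).
#' @return A list `(image, labels)`.
#' @export
augment <- function(image, labels, op, sigma = 1.5) {
  H <- dim(image)[1]; W <- dim(image)[2]
  if (op == "rotate90") {
    a <- aperm(image, c(2, 1, 3))
    image <- a[, H:1, , drop = FALSE]
    labels <- data.frame(class = labels$class, cx = 1 - labels$cy,
                         cy = labels$cx, w = labels$h, h = labels$w)
  } else if (op == "hflip") {
    image <- image[, W:1, , drop = FALSE]
    labels$cx <- 1 - labels$cx
  } else if (op == "vflip") {
    image <- image[H:1, , , drop = FALSE]
    labels$cy <- 1 - labels$cy
  } else if (op == "blur") {
    image <- clamp(EBImage::gblur(image, sigma = sigma), 0, 1)
  } else {
    stop("unknown augmentation op: ", op, call. = FALSE)
  }
  list(image = image, labels = labels)
}

#' Generate a labeled dataset with a train/test split
#'
#' Writes PNG images and YOLO-txt label files plus a tab-separated manifest
#' `image_path, label_path, split, regime, n_red, n_green`. The split is
#' stratified by regime. Per-scene fruit counts are drawn uniformly from
#' `count_range` per class.
#'
#' @param n_images Number of scenes.
#' @param out_dir Output directory (created if missing).
#' @param mix Named proportions over regimes (sparse, dense, occluded).
#' @param image_size Image side in pixels.
#' @param test_fraction Fraction held out as the test split.
#' @param count_range Inclusive integer range for per-class fruit counts.
#' @param seed Integer seed.
#' @return The manifest data frame (invisibly also written to
#'   `file.path(out_dir, "manifest.tsv")`).
#' @export
generate_dataset <- function(n_images, out_dir,
                             mix = c(sparse = 1, dense = 1, occluded = 1) / 3,
                             image_size = 416L, test_fraction = 0.25,
                             count_range = c(2L, 6L), seed = 1L) {
  stopifnot(n_images >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mix <- mix / sum(mix)
  # largest-remainder apportionment of regimes
  exact <- mix * n_images
  counts <- floor(exact)
  rem <- n_images - sum(counts)
  if (rem > 0) {
    ord <- order(exact - counts, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1L
  }
  regimes <- rep(names(counts), counts)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))
  rows <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    cfg <- scene_config(
      image_size = image_size,
      n_red = sample(count_range[1]:count_range[2], 1L),
      n_green = sample(count_range[1]:count_range[2], 1L),
      regime = regimes[i],
      seed = sample.int(.Machine$integer.max, 1L))
    sc <- generate_scene(cfg)
    img_path <- file.path(out_dir, sprintf("scene_%04d.png", i))
    lab_path <- file.path(out_dir, sprintf("scene_%04d.txt", i))
    png::writePNG(sc$image, img_path)
    write_yolo_labels(sc$labels, lab_path)
    rows[[i]] <- data.frame(image_path = img_path, label_path = lab_path,
                            split = NA_character_, regime = regimes[i],
                            n_red = sum(sc$labels$class == 0L),
                            n_green = sum(sc$labels$class == 1L))
  }
  manifest <- do.call(rbind, rows)
  # stratified split by regime
  for (g in unique(manifest$regime)) {
    idx <- which(manifest$regime == g)
    n_test <- round(test_fraction * length(idx))
    test_idx <- if (n_test > 0) sample(idx, n_test) else integer(0)
    manifest$split[idx] <- "train"
    manifest$split[test_idx] <- "test"
  }
  write_manifest(manifest, file.path(out_dir, "manifest.tsv"))
  manifest
}

#' Read / write a dataset manifest
#'
#' Tab-separated with columns
#' `image_path, label_path, split, regime, n_red, n_green`.
#'
#' @param path Manifest TSV path.
#' @return `read_manifest()` returns the manifest data frame.
#' @export
read_manifest <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_manifest
#' @param manifest Manifest data frame.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
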