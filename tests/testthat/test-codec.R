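test_that("grid spec arithmetic matches the three-scale layout", {
  spec <- grid_spec(416)
  expect_equal(spec$S, c(13L, 26L, 52L))
  expect_equal(n_predictions(spec), 10647L)
  expect_equal(grid_spec(128)$S, c(4L, 8L, 16L))
  expect_error(grid_spec(100), "config error")
})

test_that("responsible cell is the floor of the scaled center, clamped", {
  expect_equal(responsible_cell(0.5, 0.5, 13), c(row = 6L, col = 6L))
  expect_equal(responsible_cell(0.999, 0.001, 13), c(row = 0L, col = 12L))
  expect_equal(responsible_cell(1.0, 1.0, 13), c(row = 12L, col = 12L))
  expect_error(responsible_cell(1.2, 0.5, 13), "invalid label")
})

test_that("prior matching agrees with direct enumeration of the 9 IoUs", {
  anch <- toy_anchors(416L)
  set.seed(61)
  flat <- do.call(rbind, lapply(as.character(anch$grid_sizes), function(g) {
    cbind(grid = as.numeric(g), prior = 1:3, anch$allocation[[g]])
  }))
  for (r in 1:50) {
    b <- c(0.5, 0.5, runif(1, 0.02, 0.5), runif(1, 0.02, 0.5))
    mp <- match_prior(b, anch, 416)
    # oracle: co-centered IoU computed from the area formula, then argmax
    ious <- apply(flat, 1, function(f) {
      J <- min(b[3] * 416, f["w"]) * min(b[4] * 416, f["h"])
      J / (b[3] * 416 * b[4] * 416 + f["w"] * f["h"] - J)
    })
    best <- which.max(ious)
    expect_equal(mp$grid, as.integer(flat[best, "grid"]))
    expect_equal(mp$prior, as.integer(flat[best, "prior"]))
  }
  # a box exactly equal to a prior matches that prior with IoU 1
  a52 <- anch$allocation[["52"]]
  mp <- match_prior(c(0.5, 0.5, a52[1, 1] / 416, a52[1, 2] / 416), anch, 416)
  expect_equal(mp$grid, 52L)
  expect_equal(mp$prior, 1L)
  expect_equal(mp$iou, 1)
})

test_that("prior-matching ties go to the smaller-area prior", {
  # two priors contain the box with identical IoU; the smaller wins
  sizes <- cbind(w = c(10, 12, 14, 16, 20, 30, 40, 40, 80),
                 h = c(10, 12, 14, 16, 20, 30, 40, 40, 80))
  anch <- allocate_to_scales(sizes, c(4, 8, 16))
  mp <- match_prior(c(0.5, 0.5, 40 / 416, 40 / 416), anch, 416)
  dup <- anch$allocation[[as.character(mp$grid)]][mp$prior, ]
  expect_equal(unname(dup), c(40, 40))
})

test_that("encoding conserves objects and resolves collisions to the larger", {
  spec <- grid_spec(416)
  anch <- toy_anchors(416L)
  # empty labels -> all-zero target
  tg <- encode_targets(normalize_empty <- data.frame(
    class = integer(0), cx = numeric(0), cy = numeric(0),
    w = numeric(0), h = numeric(0)), spec, anch)
  expect_equal(sum(vapply(tg$t, function(a) sum(a[, , , 5]), 0)), 0)
  # one object -> exactly one objectness slot
  tg <- encode_targets(data.frame(class = 0L, cx = 0.4, cy = 0.4,
                                  w = 0.1, h = 0.1), spec, anch)
  expect_equal(sum(vapply(tg$t, function(a) sum(a[, , , 5]), 0)), 1)
  # two objects sharing center cell and best prior: the larger one keeps
  # the slot (both sizes are closest to the same large prior)
  two <- data.frame(class = c(0L, 1L), cx = 0.4, cy = 0.4,
                    w = c(0.30, 0.33), h = c(0.23, 0.25))
  mp1 <- match_prior(as.numeric(two[1, -1]), anch, 416)
  mp2 <- match_prior(as.numeric(two[2, -1]), anch, 416)
  expect_equal(mp1[c("grid", "prior")], mp2[c("grid", "prior")])
  tg <- encode_targets(two, spec, anch)
  expect_equal(tg$collisions, 1L)
  slots <- sum(vapply(tg$t, function(a) sum(a[, , , 5]), 0))
  expect_equal(slots, 1)
  # surviving slot carries the larger object's class one-hot
  g <- names(which(vapply(tg$t, function(a) sum(a[, , , 5]), 0) == 1))
  a <- tg$t[[g]]
  idx <- which(array(a[, , , 5], dim = dim(a)[1:3]) == 1, arr.ind = TRUE)
  expect_equal(a[idx[1], idx[2], idx[3], 4], 0.25)
  expect_equal(a[idx[1], idx[2], idx[3], 7], 1)  # class 1 one-hot
  expect_error(encode_targets(data.frame(class = 2L, cx = .5, cy = .5,
                                         w = .1, h = .1), spec, anch),
               "invalid label")
})

test_that("conservation: objectness slots = labels - collisions", {
  spec <- grid_spec(128)
  anch <- toy_anchors(128L)
  set.seed(77)
  for (r in 1:20) {
    labels <- random_labels(sample(0:12, 1))
    tg <- encode_targets(labels, spec, anch)
    slots <- sum(vapply(tg$t, function(a) sum(a[, , , 5]), 0))
    expect_equal(slots, nrow(labels) - tg$collisions)
  }
})

test_that("decoding emits one candidate per slot with the standard transform", {
  spec <- grid_spec(416)
  anch <- toy_anchors(416L)
  raw <- lapply(spec$S, function(S) array(0, dim = c(S, S, 3, 7)))
  names(raw) <- as.character(spec$S)
  d <- decode_raw(raw, spec, anch)
  expect_equal(nrow(d), 10647L)
  # all-zero raw: sigmoid(0) = 0.5 cell offset, exp(0) = 1 anchor scale
  cell <- d[d$grid == 13 & d$row == 6 & d$col == 6 & d$prior == 1, ]
  expect_equal(cell$cx, 6.5 / 13)
  expect_equal(cell$cy, 6.5 / 13)
  expect_equal(cell$w, unname(anch$allocation[["13"]][1, 1] / 416))
  expect_equal(cell$h, unname(anch$allocation[["13"]][1, 2] / 416))
  expect_equal(cell$confidence, 0.25)  # sigmoid(0)^2
  expect_error(decode_raw(raw[1:2], spec, anch), "shape error")
})

test_that("a single-scale 2x2 spec with one prior emits 4 candidates", {
  spec1 <- structure(list(input_size = 64L, strides = 32L, S = 2L,
                          B = 1L, C = 2L), class = "fy_gridspec")
  anch1 <- list(allocation = list("2" = cbind(w = 20, h = 24)))
  raw <- list("2" = array(0, dim = c(2, 2, 1, 7)))
  d <- decode_raw(raw, spec1, anch1)
  expect_equal(nrow(d), 4L)
  expect_equal(n_predictions(spec1), 4L)
})

test_that("encode -> represent-as-raw -> decode round-trips labels", {
  spec <- grid_spec(128)
  anch <- toy_anchors(128L)
  set.seed(90)
  for (r in 1:25) {
    labels <- random_labels(sample(1:8, 1))
    tg <- encode_targets(labels, spec, anch)
    raw <- target_to_raw(tg, spec, anch)
    d <- decode_raw(raw, spec, anch)
    top <- d[d$confidence > 0.9, ]
    expect_equal(nrow(top), nrow(labels) - tg$collisions)
    if (tg$collisions > 0) next
    # match decoded boxes back to labels within 1e-6
    for (i in seq_len(nrow(labels))) {
      dist <- abs(top$cx - labels$cx[i]) + abs(top$cy - labels$cy[i]) +
        abs(top$w - labels$w[i]) + abs(top$h - labels$h[i])
      j <- which.min(dist)
      expect_lt(dist[j], 1e-6)
      expect_equal(top$class[j], labels$class[i])
    }
  }
})

test_that("label files round-trip through the YOLO text dialect", {
  labels <- data.frame(class = c(0L, 1L), cx = c(0.25, 0.75),
                       cy = c(0.4, 0.6), w = c(0.1, 0.2), h = c(0.15, 0.1))
  path <- withr::local_tempfile(fileext = ".txt")
  write_yolo_labels(labels, path)
  back <- read_yolo_labels(path)
  expect_equal(back, labels, tolerance = 1e-6)
  write_yolo_labels(labels[0, ], path)
  expect_equal(nrow(read_yolo_labels(path)), 0L)
})
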