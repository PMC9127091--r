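test_that("Euclidean position loss matches hand arithmetic", {
  p <- c(0.5, 0.5, 0.25, 0.25)
  t <- c(0.5, 0.5, 1, 1)
  expect_equal(euclidean_position_loss(p, p), 0)
  expect_equal(euclidean_position_loss(p, t), 0.5)
  # scaling both sizes by 4 changes the value: the scale-dependence that
  # motivates the GIoU alternative
  p4 <- c(0.5, 0.5, 1, 1); t4 <- c(0.5, 0.5, 4, 4)
  expect_equal(euclidean_position_loss(p4, t4), 2)
  expect_error(euclidean_position_loss(rbind(p, p), rbind(t)), "alignment")
})

test_that("GIoU position loss matches hand arithmetic and is bounded", {
  a <- from_corners(c(0, 0, 2, 2))
  b <- from_corners(c(1, 1, 3, 3))
  expect_equal(giou_position_loss(a, a), 0)
  expect_equal(giou_position_loss(a, b), 1 - (1 / 7 - 2 / 9))
  set.seed(41)
  p <- random_boxes(300, center_range = c(-2, 2))
  t <- random_boxes(300, center_range = c(-2, 2))
  per_pair <- 1 - box_giou(p, t)$giou
  expect_true(all(per_pair >= 0 & per_pair < 2))
})

test_that("GIoU loss is scale/translation invariant; Euclidean is not", {
  set.seed(42)
  p <- random_boxes(100)
  t <- random_boxes(100)
  g0 <- giou_position_loss(p, t)
  e0 <- euclidean_position_loss(p, t)
  for (s in c(0.1, 7)) {
    expect_equal(giou_position_loss(p * s, t * s), g0, tolerance = 1e-9)
    expect_false(isTRUE(all.equal(euclidean_position_loss(p * s, t * s), e0,
                                  tolerance = 1e-6)))
  }
  shift <- cbind(2, -1, 0, 0)[rep(1, 100), ]
  expect_equal(giou_position_loss(p + shift, t + shift), g0, tolerance = 1e-9)
})

test_that("sliding a pred box away from the truth strictly increases 1-GIoU", {
  t <- box(0, 0, 1, 1)
  offs <- seq(0, 5, by = 0.25)
  l <- vapply(offs, function(o) 1 - box_giou(box(o, 0, 1, 1), t)$giou, 0)
  expect_true(all(diff(l) > 0))
})

test_that("total loss decomposes and behaves at its limits", {
  spec <- grid_spec(128)
  anch <- toy_anchors(128L)
  set.seed(43)
  labels <- random_labels(5)
  tg <- encode_targets(labels, spec, anch)
  # perfect raw predictions: inverse-decoded targets, saturated logits
  raw <- target_to_raw(tg, spec, anch, sat = 20)
  lt <- total_loss(tg, raw, spec, anch, mode = "giou")
  expect_lte(lt$total, 1e-3)
  # empty image, strongly negative objectness
  tg0 <- encode_targets(labels[0, ], spec, anch)
  raw0 <- target_to_raw(tg0, spec, anch, sat = 20)
  lt0 <- total_loss(tg0, raw0, spec, anch, mode = "giou")
  expect_equal(lt0$position, 0)
  expect_equal(lt0$classification, 0)
  expect_lt(lt0$confidence, 1e-3)
  # imperfect batch: modes differ only in the position term
  raw_noisy <- lapply(raw, function(a) a + 0.3)
  names(raw_noisy) <- names(raw)
  lg <- total_loss(tg, raw_noisy, spec, anch, mode = "giou")
  le <- total_loss(tg, raw_noisy, spec, anch, mode = "euclidean")
  expect_equal(lg$confidence, le$confidence)
  expect_equal(lg$classification, le$classification)
  expect_false(isTRUE(all.equal(lg$position, le$position)))
  # terms finite, non-negative, and summing to the total
  for (lt in list(lg, le)) {
    expect_true(all(is.finite(unlist(lt))))
    expect_true(all(unlist(lt) >= 0))
    expect_equal(lt$total,
                 lt$position + lt$confidence + lt$classification,
                 tolerance = 1e-9)
  }
  expect_error(total_loss(tg, raw, spec, anch, mode = "absolute"))
})

test_that("loss gradients on raw tensors match central differences", {
  spec <- grid_spec(64)
  anch <- toy_anchors(64L)
  set.seed(44)
  labels <- random_labels(3)
  tg <- encode_targets(labels, spec, anch)
  raw <- lapply(spec$S, function(S) {
    array(rnorm(S * S * 3 * 7, sd = 0.5), dim = c(S, S, 3, 7))
  })
  names(raw) <- as.character(spec$S)
  for (mode in c("giou", "euclidean")) {
    lg <- fruityield:::yolo_loss_grad(raw, tg, spec, anch, mode, c(1, 1, 1),
                                      want_grad = TRUE)
    for (rep in 1:20) {
      g <- sample(names(raw), 1)
      i <- sample(length(raw[[g]]), 1)
      eps <- 1e-5
      rp <- raw; rp[[g]][i] <- rp[[g]][i] + eps
      rm <- raw; rm[[g]][i] <- rm[[g]][i] - eps
      num <- (fruityield:::yolo_loss_grad(rp, tg, spec, anch, mode,
                                          c(1, 1, 1))$weighted_total -
              fruityield:::yolo_loss_grad(rm, tg, spec, anch, mode,
                                          c(1, 1, 1))$weighted_total) / (2 * eps)
      expect_equal(lg$grads[[g]][i], num, tolerance = 1e-3)
    }
  }
})
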