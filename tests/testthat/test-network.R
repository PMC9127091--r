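test_that("head outputs match the grid-spec contract at legal input sizes", {
  for (size in c(64L, 128L)) {
    net <- build_backbone(size, width_multiplier = 0.25, seed = 2)
    x <- array(0.5, dim = c(size, size, 3))
    fw <- net_forward(net, x)
    expect_equal(as.integer(names(fw$raw)), size %/% c(32L, 16L, 8L))
    for (g in names(fw$raw)) {
      S <- as.integer(g)
      expect_equal(dim(fw$raw[[g]]), c(S, S, 3L, 7L))
    }
  }
  expect_error(build_backbone(100L), "config error")
})

test_that("backpropagated parameter gradients match central differences", {
  set.seed(19)
  net <- build_backbone(64L, width_multiplier = 0.25, seed = 3)
  spec <- net$spec
  anch <- toy_anchors(64L)
  x <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
  labels <- random_labels(2)
  tg <- encode_targets(labels, spec, anch)
  fw <- net_forward(net, x, keep_cache = TRUE)
  lg <- fruityield:::yolo_loss_grad(fw$raw, tg, spec, anch, "giou",
                                    c(1, 1, 1), want_grad = TRUE)
  gp <- net_backward(net, fw$cache, lg$grads)
  lossfun <- function(n) {
    f <- net_forward(n, x)
    fruityield:::yolo_loss_grad(f$raw, tg, spec, anch, "giou",
                                c(1, 1, 1))$weighted_total
  }
  for (nm in c("stem", "d8", "f16", "head32", "head8")) {
    W <- net$params[[nm]]$W
    for (r in 1:3) {
      i <- sample(length(W), 1)
      eps <- 1e-5
      n2 <- net; n2$params[[nm]]$W[i] <- W[i] + eps
      n3 <- net; n3$params[[nm]]$W[i] <- W[i] - eps
      num <- (lossfun(n2) - lossfun(n3)) / (2 * eps)
      expect_equal(gp[[nm]]$gW[i], num,
                   tolerance = max(1e-3, 1e-3 * abs(num)))
    }
  }
})

test_that("preprocess stretches arbitrary images to the input frame", {
  img <- array(runif(80 * 60 * 3), dim = c(80, 60, 3))
  out <- preprocess(img, 64L)
  expect_equal(dim(out), c(64L, 64L, 3L))
  expect_true(all(out >= 0 & out <= 1))
  # already-sized image passes through unchanged
  img2 <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
  expect_equal(preprocess(img2, 64L), img2)
  # degenerate 1x1 image is legal
  out1 <- preprocess(array(0.3, dim = c(1, 1, 3)), 64L)
  expect_equal(dim(out1), c(64L, 64L, 3L))
})

test_that("training is deterministic and inert at zero learning rate", {
  dir <- withr::local_tempdir()
  set.seed(3)
  m <- generate_dataset(8, dir, mix = c(sparse = 1), image_size = 64L,
                        test_fraction = 0.25, count_range = c(1L, 3L),
                        seed = 12)
  anch <- toy_anchors(64L)
  cfg <- train_config(iterations = 6L, batch_size = 4L, input_size = 64L,
                      width_multiplier = 0.25, seed = 5L, eval_every = 3L,
                      eval_n = 2L)
  ck1 <- train_detector(m, anch, cfg, quiet = TRUE)
  ck2 <- train_detector(m, anch, cfg, quiet = TRUE)
  expect_identical(ck1$trace, ck2$trace)
  expect_identical(ck1$net$params, ck2$net$params)
  # zero learning rate with full-dataset batches: parameters frozen, so
  # every cycle sees the same images and the loss trace is constant
  m0 <- m; m0$split <- "train"
  cfg0 <- train_config(iterations = 5L, batch_size = nrow(m0),
                       input_size = 64L, width_multiplier = 0.25, seed = 5L,
                       learning_rate = 0, eval_every = 10L, augment = FALSE)
  ck0 <- train_detector(m0, anch, cfg0, quiet = TRUE)
  expect_lt(max(ck0$trace$total) - min(ck0$trace$total),
            1e-6 * max(1, ck0$trace$total[1]))
  expect_error(train_detector(m[m$split == "none", ], anch, cfg, quiet = TRUE),
               "empty manifest")
})

test_that("learning-rate schedule drops by the configured factor", {
  dir <- withr::local_tempdir()
  m <- generate_dataset(4, dir, mix = c(sparse = 1), image_size = 64L,
                        test_fraction = 0, count_range = c(1L, 2L), seed = 9)
  cfg <- train_config(iterations = 6L, batch_size = 2L, input_size = 64L,
                      width_multiplier = 0.25, seed = 2L, lr_drop_at = 4L,
                      lr_drop_factor = 0.1)
  ck <- train_detector(m, toy_anchors(64L), cfg, quiet = TRUE)
  expect_equal(unique(ck$trace$lr[ck$trace$iter <= 4]), 0.001)
  expect_equal(unique(ck$trace$lr[ck$trace$iter > 4]), 0.0001)
})

test_that("checkpoints round-trip through disk", {
  dir <- withr::local_tempdir()
  m <- generate_dataset(4, dir, mix = c(sparse = 1), image_size = 64L,
                        test_fraction = 0.5, count_range = c(1L, 2L), seed = 4)
  cfg <- train_config(iterations = 2L, batch_size = 2L, input_size = 64L,
                      width_multiplier = 0.25, seed = 8L, eval_every = 2L)
  ck <- train_detector(m, toy_anchors(64L), cfg, quiet = TRUE)
  path <- file.path(dir, "ck.rds")
  save_checkpoint(ck, path)
  back <- load_checkpoint(path)
  expect_identical(back$net$params, ck$net$params)
  d1 <- infer_images(ck, m$image_path[1])
  d2 <- infer_images(path, m$image_path[1])
  expect_identical(d1, d2)
})
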