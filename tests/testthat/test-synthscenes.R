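test_that("scene generation is deterministic and honors counts", {
  cfg <- scene_config(image_size = 96L, n_red = 2L, n_green = 1L,
                      regime = "sparse", seed = 7L)
  sc1 <- generate_scene(cfg)
  sc2 <- generate_scene(cfg)
  expect_identical(sc1$image, sc2$image)
  expect_identical(sc1$labels, sc2$labels)
  expect_equal(nrow(sc1$labels), 3L)
  expect_equal(sum(sc1$labels$class == 0L), 2L)
  expect_equal(sum(sc1$labels$class == 1L), 1L)
  # sparse regime: disjoint boxes
  ious <- box_iou_cross(as_box_matrix(sc1$labels), as_box_matrix(sc1$labels))
  expect_true(all(ious[upper.tri(ious)] == 0))
  # empty scene
  sc0 <- generate_scene(scene_config(image_size = 96L, n_red = 0L,
                                     n_green = 0L, seed = 1L))
  expect_equal(nrow(sc0$labels), 0L)
  expect_equal(dim(sc0$image), c(96L, 96L, 3L))
})

test_that("regime invariants hold across seeds", {
  for (seed in 1:5) {
    dn <- generate_scene(scene_config(image_size = 128L, n_red = 4L,
                                      n_green = 4L, regime = "dense",
                                      seed = seed))
    ious <- box_iou_cross(as_box_matrix(dn$labels), as_box_matrix(dn$labels))
    expect_lte(max(ious[upper.tri(ious)]), 0.4)
    oc <- generate_scene(scene_config(image_size = 128L, n_red = 3L,
                                      n_green = 3L, regime = "occluded",
                                      seed = seed))
    expect_true(all(oc$audit$occluded_fraction >= 0.4))
  }
})

test_that("sparse label boxes are mostly fruit-colored pixels", {
  for (seed in 1:4) {
    sc <- generate_scene(scene_config(image_size = 128L, n_red = 3L,
                                      n_green = 3L, regime = "sparse",
                                      seed = seed))
    # construction audit: ellipse coverage of its tight box
    expect_true(all(sc$audit$box_fill >= 0.6))
    # direct color check for red fruit: red channel dominates green inside
    reds <- sc$labels[sc$labels$class == 0L, ]
    for (i in seq_len(nrow(reds))) {
      b <- reds[i, ]
      ys <- max(1, floor((b$cy - b$h / 2) * 128)):min(128, ceiling((b$cy + b$h / 2) * 128))
      xs <- max(1, floor((b$cx - b$w / 2) * 128)):min(128, ceiling((b$cx + b$w / 2) * 128))
      frac <- mean(sc$image[ys, xs, 1] > sc$image[ys, xs, 2])
      expect_gte(frac, 0.6)
    }
  }
})

test_that("geometric augmentations transform labels consistently", {
  labels <- data.frame(class = 0L, cx = 0.2, cy = 0.3, w = 0.1, h = 0.1)
  img <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
  hf <- augment(img, labels, "hflip")
  expect_equal(hf$labels$cx, 0.8)
  expect_equal(hf$labels$cy, 0.3)
  vf <- augment(img, labels, "vflip")
  expect_equal(vf$labels$cy, 0.7)
  # rotate90 applied four times is the identity
  cur <- list(image = img, labels = labels)
  for (i in 1:4) cur <- augment(cur$image, cur$labels, "rotate90")
  expect_equal(cur$image, img)
  expect_equal(cur$labels, labels, tolerance = 1e-9)
  # blur: labels untouched, image changed
  bl <- augment(img, labels, "blur", sigma = 1)
  expect_identical(bl$labels, labels)
  expect_false(identical(bl$image, img))
  expect_error(augment(img, labels, "shear"), "unknown")
})

test_that("augmented imagery stays consistent with its labels", {
  # a fruit drawn at a known spot must still sit under its transformed box
  sc <- generate_scene(scene_config(image_size = 96L, n_red = 1L,
                                    n_green = 0L, regime = "sparse",
                                    seed = 21L))
  for (op in c("hflip", "vflip", "rotate90")) {
    tr <- augment(sc$image, sc$labels, op)
    b <- tr$labels[1, ]
    cy <- round(b$cy * 96); cx <- round(b$cx * 96)
    px <- tr$image[cy, cx, ]
    expect_gt(px[1], px[2])  # red fruit pixel at the transformed center
  }
})

test_that("dataset generation writes a stratified, consistent manifest", {
  dir <- withr::local_tempdir()
  m <- generate_dataset(30, dir, mix = c(sparse = 1, dense = 1, occluded = 1) / 3,
                        image_size = 64L, test_fraction = 0.2,
                        count_range = c(1L, 3L), seed = 31)
  expect_equal(nrow(m), 30L)
  expect_equal(as.vector(table(m$regime)), rep(10L, 3))
  expect_equal(as.vector(table(m$regime, m$split)[, "test"]), rep(2L, 3))
  expect_true(all(file.exists(m$image_path)))
  expect_true(all(file.exists(m$label_path)))
  # recorded counts equal label-file line counts per class
  for (i in seq_len(nrow(m))) {
    l <- read_yolo_labels(m$label_path[i])
    expect_equal(sum(l$class == 0L), m$n_red[i])
    expect_equal(sum(l$class == 1L), m$n_green[i])
  }
  # manifest round-trip
  back <- read_manifest(file.path(dir, "manifest.tsv"))
  expect_equal(back, m)
  # zero test fraction puts everything in train
  m2 <- generate_dataset(6, withr::local_tempdir(), mix = c(sparse = 1),
                         image_size = 64L, test_fraction = 0,
                         count_range = c(1L, 2L), seed = 5)
  expect_true(all(m2$split == "train"))
})
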