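# Tiling, dihedral augmentation, leakage-safe 3:1:1 splitting, architecture
# selection and tile normalization.

test_that("tiling produces the expected grid", {
  img <- matrix(runif(640 * 960), 640, 960)
  msk <- matrix(rbinom(640 * 960, 1, 0.2), 640, 960)
  ts <- tile_scene(img, msk, 320)
  expect_length(ts, 6)                      # floor(640/320) x floor(960/320)
  origins <- t(sapply(ts$tiles, function(t) t$origin))
  expect_equal(origins[1, ], c(0L, 0L))     # row-major from the origin
  expect_equal(origins[2, ], c(0L, 320L))

  one <- tile_scene(img[1:320, 1:320], msk[1:320, 1:320], 320)
  expect_length(one, 1)
  expect_equal(one$tiles[[1]]$origin, c(0L, 0L))

  # edge remainder discarded: one dimension too small gives zero tiles
  none <- tile_scene(img[1:319, 1:320], msk[1:319, 1:320], 320)
  expect_length(none, 0)
  expect_error(tile_scene(img[1:100, 1:100], msk[1:100, 1:100], 320), "exceeds")
})

test_that("tile content matches the source window and masks binarize", {
  img <- matrix(seq_len(64 * 64), 64, 64)
  msk <- matrix(0, 64, 64); msk[10:20, 40:50] <- 255    # 0/255 convention
  ts <- tile_scene(img, msk, 32)
  t4 <- ts$tiles[[4]]                       # origin (32, 32), row-major
  expect_equal(t4$origin, c(32L, 32L))
  expect_equal(t4$image, img[33:64, 33:64])
  expect_true(all(unlist(lapply(ts$tiles, function(t) t$mask)) %in% 0:1))
  expect_equal(sum(sapply(ts$tiles, function(t) sum(t$mask))), 11 * 11)
})

test_that("augmentation expands six-fold with co-transformed masks", {
  ts <- tile_scene(matrix(runif(64 * 64), 64, 64),
                   matrix(rbinom(64 * 64, 1, 0.3), 64, 64), 32)
  aug <- augment_tiles(ts)
  expect_length(aug, 6 * length(ts))
  tags <- sapply(aug$tiles[1:6], function(t) t$transform_tag)
  expect_setequal(tags, wn$aug_transforms)
  # image and mask share the operator
  src <- ts$tiles[[2]]
  for (k in 7:12) {
    t <- aug$tiles[[k]]
    expect_equal(t$source_id, src$source_id)
    expect_equal(t$image, wn$apply_transform(src$image, t$transform_tag))
    expect_equal(t$mask, wn$apply_transform(src$mask, t$transform_tag))
  }
  # double augmentation is rejected
  expect_error(augment_tiles(aug), "untransformed")
})

test_that("a constant tile still yields six tagged samples", {
  ts <- tile_scene(matrix(1, 32, 32), matrix(0, 32, 32), 32)
  aug <- augment_tiles(ts)
  expect_length(aug, 6)
  imgs <- lapply(aug$tiles, function(t) t$image)
  expect_true(all(sapply(imgs, function(m) identical(m, imgs[[1]]))))
  expect_length(unique(sapply(aug$tiles, function(t) t$transform_tag)), 6)
})

test_that("the dihedral operators are involutions and compose as expected", {
  x <- matrix(rnorm(25), 5, 5)
  for (tag in c("hflip", "vflip", "rot180", "transpose", "antitranspose")) {
    expect_equal(wn$apply_transform(wn$apply_transform(x, tag), tag), x,
                 label = paste(tag, "applied twice"))
  }
  # hflip o vflip = rot180
  expect_equal(wn$apply_transform(wn$apply_transform(x, "hflip"), "vflip"),
               wn$apply_transform(x, "rot180"))
  # transpose o rot180 = antitranspose
  expect_equal(wn$apply_transform(wn$apply_transform(x, "rot180"), "transpose"),
               wn$apply_transform(x, "antitranspose"))
})

test_that("splits are 3:1:1 by largest remainder, disjoint and exhaustive", {
  img <- matrix(runif(96 * 128), 96, 128)
  msk <- matrix(0, 96, 128)
  ts <- tile_scene(img, msk, 16)           # 48 source tiles
  ts <- split_tiles(ts, c(3, 1, 1), seed = 5)
  tb <- table(ts$split_labels)
  expect_equal(unname(tb[c("train", "val", "test")]), c(29, 10, 9),
               ignore_attr = TRUE)          # 48 * (3,1,1)/5 largest-remainder
  expect_equal(sum(tb), length(ts))
  # reproducible
  ts2 <- split_tiles(ts, c(3, 1, 1), seed = 5)
  expect_identical(ts$split_labels, ts2$split_labels)
  ts3 <- split_tiles(ts, c(3, 1, 1), seed = 6)
  expect_false(identical(ts$split_labels, ts3$split_labels))
})

test_that("augmented variants of one source tile never straddle splits", {
  ts <- tiny_tileset(seed = 21)
  aug <- augment_tiles(ts)
  by_src <- split(aug$split_labels,
                  sapply(aug$tiles, function(t) t$source_id))
  expect_true(all(vapply(by_src, function(l) length(unique(l)) == 1L, TRUE)))
  # split after augmentation groups by source as well
  aug2 <- split_tiles(augment_tiles(tile_scene(
    matrix(runif(64 * 64), 64, 64), matrix(0, 64, 64), 16)),
    c(3, 1, 1), seed = 3)
  by_src2 <- split(aug2$split_labels,
                   sapply(aug2$tiles, function(t) t$source_id))
  expect_true(all(vapply(by_src2, function(l) length(unique(l)) == 1L, TRUE)))
})

test_that("tile size selects the architecture depth", {
  expect_identical(select_architecture(320), 3L)
  expect_identical(select_architecture(450), 4L)
  expect_identical(select_architecture(550), 5L)
  # half-open shared endpoints
  expect_identical(select_architecture(400), 4L)
  expect_identical(select_architecture(500), 5L)
  expect_identical(select_architecture(600), 5L)
  expect_error(select_architecture(256), "choose L manually")
  expect_error(select_architecture(601), "choose L manually")
})

test_that("tile normalization is a min-max map onto [0,1], idempotent", {
  expect_equal(normalize_tile(matrix(c(0, 2, 4, 4), 2, 2)),
               matrix(c(0, 0.5, 1, 1), 2, 2))
  expect_equal(normalize_tile(matrix(7, 3, 3)), matrix(0, 3, 3))
  x <- matrix(rnorm(36), 6, 6)
  expect_equal(normalize_tile(normalize_tile(x)), normalize_tile(x))
  expect_error(normalize_tile(matrix(c(1, NA, 2, 3), 2, 2)), "finite")
})
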