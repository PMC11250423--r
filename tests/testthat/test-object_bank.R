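test_that("luminance_value is the mean over all pixels, background included", {
  expect_equal(luminance_value(matrix(0, 28, 28)), 0)
  expect_equal(luminance_value(matrix(255, 28, 28)), 255)
  expect_equal(luminance_value(matrix(c(0, 0, 255, 255), 2, 2)), 127.5)
  expect_error(luminance_value(matrix(numeric(0), 0, 0)), "non-empty")
  expect_error(luminance_value(matrix(-1, 2, 2)), "0, 255")
  expect_error(luminance_value(matrix(300, 2, 2)), "0, 255")
})

test_that("luminance levels follow the 255/8 thresholds, closed below", {
  expect_identical(luminance_level(0), "low")
  expect_identical(luminance_level(31.875 - 1e-9), "low")
  expect_identical(luminance_level(31.875), "medium_low")
  expect_identical(luminance_level(63.75 - 1e-9), "medium_low")
  expect_identical(luminance_level(63.75), "medium_high")
  expect_identical(luminance_level(95.625 - 1e-9), "medium_high")
  expect_identical(luminance_level(95.625), "high")
  expect_identical(luminance_level(255), "high")
  expect_error(luminance_level(-0.1))
  expect_error(luminance_level(255.1))
})

test_that("luminance levels partition [0,255] with no gaps or overlaps", {
  grid <- seq(0, 255, by = 0.517)
  lv <- luminance_level(grid)
  expect_true(all(lv %in% luminance_levels()))
  expect_true(all(nchar(lv) > 0))
  # monotone: level index is non-decreasing in the value
  idx <- match(lv, luminance_levels())
  expect_true(all(diff(idx) >= 0))
  expect_setequal(unique(lv), luminance_levels())
})

test_that("rotation follows the up/left/down/right counter-clockwise convention", {
  m <- matrix(c(1, 3, 2, 4), 2, 2) # rows: (1,2) / (3,4)
  expect_identical(rotate_object(m, "up"), m)
  expect_identical(rotate_object(m, "left"), matrix(c(2, 1, 4, 3), 2, 2))
  expect_identical(rotate_object(rotate_object(m, "down"), "down"), m)
  left4 <- Reduce(function(x, .) rotate_object(x, "left"), 1:4, m)
  expect_identical(left4, m)
  x <- matrix(runif(25, 0, 255), 5, 5)
  expect_equal(luminance_value(rotate_object(x, "left")), luminance_value(x))
  expect_equal(luminance_value(rotate_object(x, "right")), luminance_value(x))
  expect_error(rotate_object(matrix(0, 2, 3), "up"), "square")
  expect_error(rotate_object(matrix(0, 2, 2), "sideways"), "orientation")
})

test_that("glyph prototypes are rotation-asymmetric", {
  for (cn in bindmap:::glyph_classes()) {
    proto <- bindmap:::glyph_mask(cn, 16)
    rot <- proto
    for (k in 1:3) {
      rot <- bindmap:::rot90_ccw(rot)
      expect_false(identical(rot, proto), label = sprintf("%s rot %d", cn, k))
    }
  }
})

test_that("glyph banks are deterministic and correctly labelled", {
  cfg <- bank_config(n_per_class = 10, obj_size = 16, seed = 7)
  bank <- build_bank(cfg)
  expect_s3_class(bank$meta, "tbl_df")
  expect_equal(nrow(bank$meta), 40)
  expect_equal(unname(table(bank$meta$class_label)), rep(10L, 4),
               ignore_attr = TRUE)
  # labels are consistent with the rendered pixels
  lum <- vapply(bank$images, luminance_value, numeric(1))
  expect_equal(bank$meta$luminance_value, lum)
  expect_identical(bank$meta$luminance_level, luminance_level(lum))
  expect_true(all(vapply(bank$images, function(im) {
    all(im >= 0 & im <= 255) && all(dim(im) == 16)
  }, logical(1))))
  # bit-identical rebuild from the same seed
  expect_identical(bank, build_bank(cfg))
  expect_false(identical(bank, build_bank(bank_config(n_per_class = 10,
                                                      obj_size = 16, seed = 8))))
})

test_that("equal per-class luminance targets remove the identity dependency", {
  bank <- build_bank(desk_bank_config(tops = TRUE, n_per_class = 80, seed = 3))
  means <- tapply(bank$meta$luminance_value, bank$meta$class_label, mean)
  se <- tapply(bank$meta$luminance_value, bank$meta$class_label, sd) / sqrt(80)
  expect_lt(max(means) - min(means), 3 * max(se))
})

test_that("classes are separable by a location-free nearest-centroid read-out", {
  bank <- the_bank()
  X <- t(vapply(bank$images, as.vector, numeric(16 * 16)))
  X <- X / pmax(rowMeans(X), 1e-9) # normalize away luminance
  cls <- bank$meta$class_label
  centroids <- vapply(unique(cls), function(cn) colMeans(X[cls == cn, ]),
                      numeric(ncol(X)))
  pred <- unique(cls)[apply(X %*% centroids, 1, which.max)]
  expect_gt(mean(pred == cls), 0.5) # chance = 0.25
})

test_that("the IDX adapter builds a bank from synthetic Fashion-MNIST files", {
  # synthetic stand-in images: per-class blobs at class-dependent intensity
  dir <- withr::local_tempdir()
  set.seed(42)
  imgs <- list(); labs <- integer(0)
  lmap <- bindmap:::fashion_label_map()
  for (cn in c("t-shirt", "pant", "shoe", "bag")) {
    for (i in 1:6) {
      im <- matrix(0, 28, 28)
      im[8:24, 6:22] <- sample(30:220, 1)
      if (cn == "bag" && i <= 4) im[1:3, 10:18] <- 200 # handle arc
      imgs[[length(imgs) + 1]] <- im
      labs <- c(labs, lmap[[cn]])
    }
  }
  write_idx_images(file.path(dir, "train-images-idx3-ubyte"), imgs)
  write_idx_labels(file.path(dir, "train-labels-idx1-ubyte"), labs)
  cfg <- bank_config(source = "fashion_mnist", n_per_class = 4, obj_size = 28,
                     seed = 1, fashion_dir = dir)
  bank <- build_bank(cfg)
  expect_equal(nrow(bank$meta), 16)
  expect_identical(bank$meta$luminance_level,
                   luminance_level(bank$meta$luminance_value))
  # only the four bags with a handle arc qualify
  expect_true(all(vapply(
    bank$images[bank$meta$class_label == "bag"],
    bindmap:::has_top_mass, logical(1))))
  # requesting more bags than have handles fails loudly
  cfg5 <- bank_config(source = "fashion_mnist", n_per_class = 5, obj_size = 28,
                      seed = 1, fashion_dir = dir)
  expect_error(build_bank(cfg5), "bag")
  expect_error(build_bank(bank_config(source = "fashion_mnist",
                                      fashion_dir = tempfile())), "missing|not found")
})

test_that("bank export/import round-trips images and manifest", {
  bank <- tiny_bank(seed = 2, n = 3)
  dir <- withr::local_tempdir()
  write_bank(bank, dir)
  back <- read_bank(dir)
  expect_equal(back$meta$class_label, bank$meta$class_label)
  expect_equal(back$meta$luminance_value, bank$meta$luminance_value,
               tolerance = 1 / 255)
  expect_true(all(vapply(seq_along(bank$images), function(i) {
    max(abs(back$images[[i]] - bank$images[[i]])) <= 1
  }, logical(1))))
})
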