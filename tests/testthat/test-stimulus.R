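test_that("grid centers partition the canvas and patches never overlap", {
  g <- grid_centers(140, 3, 3, 28)
  expect_equal(nrow(g), 9)
  expect_equal(g$location, 1:9)
  expect_equal(g$row, rep(1:3, each = 3)) # row-major: 1 = top-left
  # bounding boxes of 28 px patches at any two distinct centers are disjoint
  boxes <- cbind(g$top, g$top + 27, g$left, g$left + 27)
  for (i in 1:8) {
    for (j in (i + 1):9) {
      overlap <- boxes[i, 1] <= boxes[j, 2] && boxes[j, 1] <= boxes[i, 2] &&
        boxes[i, 3] <= boxes[j, 4] && boxes[j, 3] <= boxes[i, 4]
      expect_false(overlap, label = sprintf("boxes %d,%d", i, j))
    }
  }
  expect_true(all(boxes >= 1) && all(boxes <= 140))
  g1 <- grid_centers(140, 1, 1, 28)
  expect_equal(c(g1$cy, g1$cx), c(70, 70))
  expect_error(grid_centers(30, 3, 3, 28), "smaller than object")
})

test_that("scenes have distinct locations and variant constraints hold", {
  bank <- the_bank()
  cfg <- desk_dataset_config(n_images = 30, seed = 3)
  with_seed <- bindmap:::with_seed
  with_seed(1, {
    for (k in 1:25) {
      sc <- sample_scene(bank, cfg, compose = FALSE)
      expect_equal(nrow(sc$objects), 3)
      expect_false(anyDuplicated(sc$objects$location) > 0)
      expect_false(anyDuplicated(sc$objects$exemplar_id) > 0)
      expect_true(all(sc$objects$location %in% 1:9))
    }
  })
  # corner-locations variant
  cfg4 <- desk_dataset_config(variant = "equal_classes", n_images = 30, seed = 3)
  with_seed(1, {
    for (k in 1:10) {
      sc <- sample_scene(bank, cfg4, compose = FALSE)
      expect_true(all(sc$objects$location %in% c(1, 3, 7, 9)))
    }
  })
  # every attribute realizes exactly four classes in an equal-classes dataset
  ds4 <- generate_dataset(build_bank(desk_bank_config(n_per_class = 60, seed = 2)),
                          desk_dataset_config(variant = "equal_classes",
                                              n_images = 400, seed = 8),
                          canvases = FALSE)
  r4 <- ds4$train$records
  expect_setequal(unique(r4$location), c(1, 3, 7, 9))
  expect_equal(dplyr::n_distinct(r4$identity), 4)
  expect_equal(dplyr::n_distinct(r4$luminance_level), 4)
  expect_equal(dplyr::n_distinct(r4$orientation), 4)
  expect_error(dataset_config(n_objects = 10), "cannot place")
})

test_that("unique-attributes scenes never repeat any attribute", {
  bank <- the_bank()
  cfg <- desk_dataset_config(variant = "unique_attributes", n_images = 300,
                             seed = 9)
  ds <- generate_dataset(bank, cfg, canvases = FALSE)
  recs <- dplyr::bind_rows(ds$train$records, ds$val$records, ds$test$records,
                           .id = "split")
  dup <- recs |>
    dplyr::group_by(.data$split, .data$scene_id) |>
    dplyr::summarise(
      bad = anyDuplicated(.data$identity) + anyDuplicated(.data$luminance_level) +
        anyDuplicated(.data$orientation) + anyDuplicated(.data$location),
      .groups = "drop")
  expect_equal(sum(dup$bad), 0)
})

test_that("a canvas is exactly the disjoint union of its rotated patches", {
  bank <- the_bank()
  cfg <- desk_dataset_config(n_images = 10, seed = 21)
  sc <- bindmap:::with_seed(4, sample_scene(bank, cfg))
  g <- grid_centers(56, 3, 3, 16)
  acc <- matrix(0, 56, 56)
  for (i in 1:3) {
    r <- sc$objects[i, ]
    patch <- rotate_object(bank$images[[r$exemplar_id]], r$orientation)
    gi <- g[g$location == r$location, ]
    acc[gi$top:(gi$top + 15), gi$left:(gi$left + 15)] <-
      acc[gi$top:(gi$top + 15), gi$left:(gi$left + 15)] + patch
  }
  expect_identical(sc$canvas, acc)
  expect_equal(sum(sc$canvas), sum(vapply(1:3, function(i) {
    sum(bank$images[[sc$objects$exemplar_id[i]]])
  }, numeric(1))))
})

test_that("datasets split 2/3, 1/6, 1/6 and are reproducible from the seed", {
  bank <- the_bank()
  ds <- generate_dataset(bank, desk_dataset_config(n_images = 120, seed = 2),
                         canvases = FALSE)
  expect_equal(c(ds$train$n, ds$val$n, ds$test$n), c(80, 20, 20))
  # the paper-scale arithmetic
  for (n in c(6000, 12000)) {
    cfg <- dataset_config(n_images = n)
    expect_equal(round(n * cfg$split_fractions[1:2]), c(2 * n / 3, n / 6))
  }
  a <- generate_dataset(bank, desk_dataset_config(n_images = 20, seed = 77))
  b <- generate_dataset(bank, desk_dataset_config(n_images = 20, seed = 77))
  expect_identical(a$train$x, b$train$x)
  expect_identical(a$test$records, b$test$records)
  c2 <- generate_dataset(bank, desk_dataset_config(n_images = 20, seed = 78))
  expect_false(identical(a$train$x, c2$train$x))
})

test_that("dataset write/read round-trips scenes, records and config", {
  bank <- the_bank()
  ds <- generate_dataset(bank, desk_dataset_config(n_images = 12, seed = 6))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(back$train$n, ds$train$n)
  expect_equal(back$train$x, ds$train$x)
  expect_equal(back$test$x, ds$test$x)
  expect_equal(as.data.frame(back$val$records), as.data.frame(ds$val$records),
               tolerance = 1e-12)
  expect_equal(dplyr::n_distinct(back$train$records$scene_id) * 3,
               nrow(back$train$records))
  # tampered sidecar -> warning
  cfg <- jsonlite::read_json(file.path(dir, "config.json"))
  cfg$seed <- 999
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  expect_warning(read_dataset(dir), "fingerprint")
  expect_error(read_dataset(withr::local_tempdir()), "sidecar")
})
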