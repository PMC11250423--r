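test_that("map keys follow the printed class orders", {
  classes <- default_classes()
  r <- make_records(c("pant", "shoe", "t-shirt"),
                    c("high", "low", "low"),
                    c("down", "up", "right"),
                    c(5, 1, 6))
  expect_equal(map_key(r, "location", classes), c(5, 1, 6))
  # restricted location set: keys are ranks within the allowed set
  cls4 <- default_classes(locations = c(1, 3, 7, 9))
  r4 <- make_records("pant", "low", "up", 7)
  expect_equal(map_key(r4, "location", cls4), 3)
  expect_equal(map_key(r, "identity", classes), c(2, 3, 1))
  expect_equal(map_key(r, "luminance", classes), c(4, 1, 1))
  expect_equal(map_key(r, "orientation", classes), c(3, 1, 4))
  expect_error(map_key(r, "colour", classes), "unknown map")
})

test_that("ordering sorts by key with location tie-break and records tie groups", {
  classes <- default_classes()
  # location map, objects at 5, 1, 6 -> object at 1 first, then 5, then 6
  r <- make_records(c("pant", "shoe", "t-shirt"),
                    c("high", "low", "low"),
                    c("down", "up", "right"), c(5, 1, 6))
  o <- order_objects(r, "location", classes)
  expect_equal(o$permutation, c(2, 1, 3))
  expect_length(o$tie_groups, 0)
  # luminance map: the two low objects occupy the first two slots, tied
  o2 <- order_objects(r, "luminance", classes)
  expect_equal(o2$permutation[3], 1)
  expect_equal(sort(o2$permutation[1:2]), c(2, 3))
  expect_equal(o2$tie_groups, list(1:2))
  # two pants + one bag under the identity map: pants tied in slots 1-2
  r3 <- make_records(c("bag", "pant", "pant"),
                     c("low", "medium_low", "high"),
                     c("up", "up", "left"), c(9, 4, 2))
  o3 <- order_objects(r3, "identity", classes)
  expect_equal(o3$permutation, c(3, 2, 1)) # pant@2 before pant@4, bag last
  expect_equal(o3$tie_groups, list(1:2))
  # single object
  o1 <- order_objects(r3[1, ], "identity", classes)
  expect_equal(o1$permutation, 1)
})

test_that("target encodings read attributes in map order with shared slots", {
  classes <- default_classes()
  # task = location under its own map decodes to ascending locations
  r <- make_records(c("pant", "shoe", "bag"),
                    c("high", "low", "medium_low"),
                    c("down", "up", "right"), c(7, 2, 5))
  enc <- encode_targets(r, "location", "location", classes)
  expect_equal(classes$location[enc$class_idx$location], c(2, 5, 7))
  # task = identity, map = location: (pant@7, shoe@2, bag@5) -> shoe, bag, pant
  enc2 <- encode_targets(r, "identity", "location", classes)
  expect_equal(classes$identity[enc2$class_idx$identity],
               c("shoe", "bag", "pant"))
  # two-attribute task under the identity map: both groups share the ordering,
  # so the location group lists the t-shirt's location first
  r3 <- make_records(c("shoe", "t-shirt", "pant"),
                     c("low", "high", "medium_low"),
                     c("up", "left", "down"), c(3, 8, 1))
  enc3 <- encode_targets(r3, c("identity", "location"), "identity", classes)
  expect_equal(classes$identity[enc3$class_idx$identity],
               c("t-shirt", "pant", "shoe"))
  expect_equal(classes$location[enc3$class_idx$location], c(8, 1, 3))
  # one-hot matrices are valid and consistent with the class indices
  for (a in names(enc3$onehot)) {
    expect_equal(rowSums(enc3$onehot[[a]]), rep(1, 3))
    expect_equal(max.col(enc3$onehot[[a]]), enc3$class_idx[[a]])
  }
  expect_error(encode_targets(r3, character(0), "identity", classes))
})

test_that("encodings are invariant to the input order of the records", {
  classes <- default_classes()
  bank <- the_bank()
  cfg <- desk_dataset_config(n_images = 5, seed = 1)
  for (k in 1:20) {
    sc <- bindmap:::with_seed(100 + k, sample_scene(the_bank(), cfg, compose = FALSE))
    shuf <- sc$objects[sample(3), ]
    for (m in c("location", "identity", "luminance", "orientation")) {
      a <- encode_targets(sc$objects, c("identity", "location"), m, classes)
      b <- encode_targets(shuf, c("identity", "location"), m, classes)
      expect_equal(a$class_idx, b$class_idx)
    }
  }
})

test_that("the location map is relative: joint translation preserves order", {
  classes <- default_classes()
  r <- make_records(c("pant", "shoe", "bag"),
                    c("high", "low", "medium_low"),
                    c("down", "up", "right"), c(1, 5, 6))
  ord_ids <- function(rec) rec$identity[order_objects(rec, "location",
                                                      classes)$permutation]
  base <- ord_ids(r)
  shift_col <- r; shift_col$location <- r$location + 1L      # one column right
  shift_row <- r; shift_row$location <- r$location + 3L      # one row down
  expect_equal(ord_ids(shift_col), base)
  expect_equal(ord_ids(shift_row), base)
})

test_that("prediction scoring counts heads, images, and free tie permutations", {
  classes <- default_classes()
  r <- make_records(c("pant", "pant", "bag"),
                    c("low", "high", "medium_low"),
                    c("up", "left", "down"), c(4, 2, 9))
  truth <- encode_targets(r, "identity", "identity", classes)
  perfect <- list(identity = truth$onehot$identity)
  expect_equal(score_predictions(perfect, truth), 1)
  # one wrong head out of three
  one_off <- perfect
  one_off$identity[3, ] <- rev(one_off$identity[3, ])
  expect_equal(score_predictions(one_off, truth), 2 / 3)
  expect_equal(score_predictions(one_off, truth, mode = "per_image"), 0)
  # tied pair reported in swapped order: free scoring forgives, canonical not
  truth_loc <- encode_targets(r, c("identity", "location"), "identity", classes)
  swapped <- lapply(truth_loc$onehot, function(m) m[c(2, 1, 3), ])
  expect_equal(score_predictions(swapped, truth_loc, tie_policy = "canonical"),
               4 / 6) # identity heads still match (both pants), locations not
  expect_equal(score_predictions(swapped, truth_loc, tie_policy = "free"), 1)
  expect_error(score_predictions(list(identity = diag(3)), truth), "shape")
})

test_that("ordering agrees with brute-force permutation search on random scenes", {
  classes <- default_classes()
  cfg <- desk_dataset_config(n_images = 5, seed = 1)
  brute <- function(records, m) {
    keys <- map_key(records, m, classes)
    locs <- match(records$location, sort(classes$location))
    perms <- lapply(bindmap:::all_perms(nrow(records)), unlist)
    strs <- vapply(perms, function(p) {
      paste(sprintf("%02d%02d", keys[p], locs[p]), collapse = "")
    }, character(1))
    perms[[order(strs)[1]]]
  }
  for (k in 1:30) {
    sc <- bindmap:::with_seed(500 + k, sample_scene(the_bank(), cfg, compose = FALSE))
    for (m in c("location", "identity", "luminance", "orientation")) {
      expect_equal(order_objects(sc$objects, m, classes)$permutation,
                   brute(sc$objects, m), label = sprintf("seed %d map %s", k, m))
    }
  }
})
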