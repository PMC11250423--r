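# Multi-object scene composition on a square black canvas.

#' Grid-cell centers on a square canvas
#'
#' Partitions the canvas into `rows x cols` equal cells and returns the
#' (0-based, continuous) pixel center of each cell in row-major order
#' (location 1 = top-left, reading left to right, then top to bottom).
#'
#' @param canvas_size Canvas side length in pixels.
#' @param rows,cols Grid dimensions.
#' @param obj_size Object patch side length; every cell must be able to hold
#'   a patch without touching its neighbours.
#' @return A data.frame with `location`, `row`, `col`, `cy`, `cx` (centers)
#'   and `top`, `left` (1-based top-left placement indices for an
#'   `obj_size` patch).
#' @examples
#' grid_centers(140, 3, 3, 28)
#' @export
grid_centers <- function(canvas_size, rows = 3, cols = 3, obj_size = 28) {
  ch <- canvas_size / rows
  cw <- canvas_size / cols
  fail_unless(ch >= obj_size && cw >= obj_size,
              "grid cell (%.1f x %.1f px) smaller than object (%d px)",
              ch, cw, obj_size)
  loc <- seq_len(rows * cols)
  r <- (loc - 1) %/% cols + 1
  c <- (loc - 1) %% cols + 1
  cy <- (r - 0.5) * ch
  cx <- (c - 0.5) * cw
  data.frame(
    location = loc, row = r, col = c, cy = cy, cx = cx,
    top = floor(cy - obj_size / 2) + 1,
    left = floor(cx - obj_size / 2) + 1
  )
}

dataset_variants <- function() {
  c("original", "equal_classes", "unique_attributes",
    "original_tops", "equal_classes_tops", "unique_attributes_tops")
}

# Structural variant (the "_tops" suffix only signals which bank is used).
variant_base <- function(variant) sub("_tops$", "", variant)

#' Configure a scene dataset
#'
#' @param variant One of `"original"`, `"equal_classes"`,
#'   `"unique_attributes"`, or the same with a `"_tops"` suffix (identical
#'   structure, intended for a bank of four visually similar "tops" classes).
#'   `original`: three objects at three of nine locations, identities,
#'   luminance levels and orientations free to repeat.  `equal_classes`:
#'   locations restricted to the four corners `{1, 3, 7, 9}` so every
#'   attribute has four classes.  `unique_attributes`: the three objects have
#'   pairwise distinct identities, luminance levels, orientations and
#'   locations.
#' @param n_images Total number of scenes (split 2/3 train, 1/6 validation,
#'   1/6 test).
#' @param canvas_size Canvas side length in pixels.
#' @param n_objects Objects per scene.
#' @param allowed_locations Grid locations the variant may use; defaults to
#'   `1:9` or `c(1, 3, 7, 9)` for `equal_classes`.
#' @param split_fractions Train/validation/test fractions, summing to 1.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return A `dataset_config` list.
#' @export
dataset_config <- function(variant = "original",
                           n_images = 6000,
                           canvas_size = 140,
                           n_objects = 3,
                           allowed_locations = NULL,
                           split_fractions = c(2 / 3, 1 / 6, 1 / 6),
                           seed = 1L) {
  fail_unless(variant %in% dataset_variants(), "unknown variant '%s'", variant)
  base <- variant_base(variant)
  if (is.null(allowed_locations)) {
    allowed_locations <- if (base == "equal_classes") c(1L, 3L, 7L, 9L) else 1:9
  }
  fail_unless(all(allowed_locations %in% 1:9), "allowed_locations must be in 1..9")
  fail_unless(abs(sum(split_fractions) - 1) < 1e-12, "split fractions must sum to 1")
  fail_unless(n_objects <= length(allowed_locations),
              "cannot place %d objects on %d allowed locations",
              n_objects, length(allowed_locations))
  structure(
    list(variant = variant, n_images = as.integer(n_images),
         canvas_size = as.integer(canvas_size), n_objects = as.integer(n_objects),
         allowed_locations = as.integer(sort(allowed_locations)),
         split_fractions = split_fractions, seed = as.integer(seed)),
    class = "dataset_config"
  )
}

# Sample attribute records for one scene; consumes the current RNG stream.
sample_scene_records <- function(bank, config) {
  n <- config$n_objects
  locs <- sample(config$allowed_locations, n)
  base <- variant_base(config$variant)
  if (base == "unique_attributes") {
    cls_set <- bank$config$class_names
    fail_unless(length(cls_set) >= n,
                "unique_attributes needs >= %d identity classes", n)
    fail_unless(length(luminance_levels()) >= n,
                "unique_attributes needs >= %d luminance levels", n)
    orients <- sample(orientations(), n)
    for (try in seq_len(500)) {
      ids_cls <- sample(cls_set, n)
      levels <- sample(luminance_levels(), n)
      ex <- integer(n)
      ok <- TRUE
      for (i in seq_len(n)) {
        pool <- which(bank$meta$class_label == ids_cls[i] &
                        bank$meta$luminance_level == levels[i] &
                        !(bank$meta$exemplar_id %in% ex[seq_len(i - 1)]))
        if (length(pool) == 0) { ok <- FALSE; break }
        ex[i] <- bank$meta$exemplar_id[pool[[sample.int(length(pool), 1)]]]
      }
      if (ok) break
      if (try == 500) {
        missing_cls <- !all(cls_set %in% bank$meta$class_label)
        stop(sprintf(
          "unique_attributes unsatisfiable: no exemplar for some (%s) combination",
          if (missing_cls) "identity" else "identity, luminance_level"
        ), call. = FALSE)
      }
    }
  } else {
    ex <- bank$meta$exemplar_id[sample.int(nrow(bank$meta), n)]
    orients <- sample(orientations(), n, replace = TRUE)
  }
  m <- bank$meta[match(ex, bank$meta$exemplar_id), ]
  tibble::tibble(
    slot = seq_len(n),
    exemplar_id = ex,
    identity = m$class_label,
    luminance_value = m$luminance_value,
    luminance_level = m$luminance_level,
    orientation = orients,
    location = as.integer(locs)
  )
}

compose_canvas <- function(bank, records, config) {
  grid <- grid_centers(config$canvas_size, 3, 3, bank$config$obj_size)
  s <- bank$config$obj_size
  canvas <- matrix(0, config$canvas_size, config$canvas_size)
  for (i in seq_len(nrow(records))) {
    patch <- rotate_object(bank$images[[records$exemplar_id[i]]],
                           records$orientation[i])
    g <- grid[grid$location == records$location[i], ]
    canvas[g$top:(g$top + s - 1), g$left:(g$left + s - 1)] <- patch
  }
  canvas
}

#' Sample one multi-object scene
#'
#' Draws `n_objects` exemplars without replacement from the bank, assigns
#' them distinct grid locations (and, under `unique_attributes`, pairwise
#' distinct identities, luminance levels and orientations), and composes them
#' on a black canvas.  Object bounding boxes never overlap: each patch sits
#' inside its own grid cell.
#'
#' @param bank An `object_bank`.
#' @param config A [dataset_config()].
#' @param compose If `FALSE`, skip canvas composition and return records only.
#' @return A list with `canvas` (matrix, or `NULL`) and `objects` (tibble of
#'   per-object attribute records).
#' @export
sample_scene <- function(bank, config, compose = TRUE) {
  records <- sample_scene_records(bank, config)
  canvas <- if (compose) compose_canvas(bank, records, config) else NULL
  list(canvas = canvas, objects = records)
}

#' Generate a train/validation/test scene dataset
#'
#' Scenes are generated deterministically from `config$seed` and partitioned
#' into train/validation/test by the configured fractions (2/3, 1/6, 1/6 by
#' default: 6000 scenes give 4000/1000/1000).
#'
#' @param bank An `object_bank`.
#' @param config A [dataset_config()].
#' @param canvases If `FALSE`, only attribute records are generated (fast
#'   path for structural checks).
#' @return A `scene_dataset`: list with `train`, `val`, `test` (each holding
#'   `x`, an `n x canvas_size^2` pixel matrix in `[0, 255]` with column-major
#'   flattening, and `records`, one tibble row per object with a `scene_id`
#'   column), plus the `config` and the bank config.
#' @export
generate_dataset <- function(bank, config, canvases = TRUE) {
  n <- config$n_images
  n_tr <- round(n * config$split_fractions[1])
  n_va <- round(n * config$split_fractions[2])
  n_te <- n - n_tr - n_va
  sizes <- c(train = n_tr, val = n_va, test = n_te)
  d <- config$canvas_size^2
  with_seed(config$seed, {
    splits <- lapply(names(sizes), function(sp) {
      ns <- sizes[[sp]]
      x <- if (canvases) matrix(0, ns, d) else NULL
      recs <- vector("list", ns)
      for (i in seq_len(ns)) {
        sc <- sample_scene(bank, config, compose = canvases)
        if (canvases) x[i, ] <- as.vector(sc$canvas)
        recs[[i]] <- tibble::tibble(scene_id = i, sc$objects)
      }
      list(x = x, records = dplyr::bind_rows(recs), n = ns)
    })
    names(splits) <- names(sizes)
    structure(c(splits, list(config = config, bank_config = bank$config)),
              class = "scene_dataset")
  })
}

#' @export
print.scene_dataset <- function(x, ...) {
  cat(sprintf(
    "<scene_dataset> variant '%s': %d/%d/%d train/val/test scenes, %dpx canvas, %d objects each\n",
    x$config$variant, x$train$n, x$val$n, x$test$n,
    x$config$canvas_size, x$config$n_objects))
  invisible(x)
}

config_fingerprint <- function(config) {
  seed_for(0L, paste(vapply(config, function(v) paste(format(v), collapse = ","),
                            character(1)), collapse = ";"))
}

#' Write / read a scene dataset on disk
#'
#' Scenes are written as 8-bit grayscale PNGs (one per scene, per split),
#' attribute records as one CSV row per object (`scene_id`, `slot`,
#' `exemplar_id`, `identity`, `luminance_value`, `luminance_level`,
#' `orientation`, `location`) and the configuration as a JSON sidecar with a
#' fingerprint.  Reading verifies the fingerprint and warns on mismatch; the
#' round-trip is lossless.
#'
#' @param dataset A `scene_dataset`.
#' @param path Directory to write into.
#' @return `write_dataset()` the path, invisibly; `read_dataset()` the
#'   dataset.
#' @export
write_dataset <- function(dataset, path) {
  for (sp in c("train", "val", "test")) {
    dd <- file.path(path, sp)
    dir.create(dd, recursive = TRUE, showWarnings = FALSE)
    cs <- dataset$config$canvas_size
    if (!is.null(dataset[[sp]]$x)) {
      for (i in seq_len(dataset[[sp]]$n)) {
        png::writePNG(matrix(dataset[[sp]]$x[i, ], cs, cs) / 255,
                      file.path(dd, sprintf("scene_%05d.png", i)))
      }
    }
    write.csv(dataset[[sp]]$records, file.path(dd, "records.csv"),
              row.names = FALSE)
  }
  sidecar <- c(unclass(dataset$config),
               list(fingerprint = config_fingerprint(dataset$config)))
  jsonlite::write_json(sidecar, file.path(path, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  cfg_path <- file.path(path, "config.json")
  fail_unless(file.exists(cfg_path), "missing config.json sidecar under %s", path)
  cfg <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
  config <- dataset_config(variant = cfg$variant, n_images = cfg$n_images,
                           canvas_size = cfg$canvas_size, n_objects = cfg$n_objects,
                           allowed_locations = cfg$allowed_locations,
                           split_fractions = cfg$split_fractions, seed = cfg$seed)
  if (!identical(config_fingerprint(config), cfg$fingerprint)) {
    warning("config fingerprint mismatch: sidecar may be stale", call. = FALSE)
  }
  splits <- lapply(c(train = "train", val = "val", test = "test"), function(sp) {
    dd <- file.path(path, sp)
    records <- tibble::as_tibble(read.csv(file.path(dd, "records.csv"),
                                          stringsAsFactors = FALSE))
    ns <- length(unique(records$scene_id))
    pngs <- list.files(dd, pattern = "^scene_.*\\.png$")
    x <- NULL
    if (length(pngs) > 0) {
      x <- matrix(0, ns, config$canvas_size^2)
      for (i in seq_len(ns)) {
        x[i, ] <- as.vector(round(
          png::readPNG(file.path(dd, sprintf("scene_%05d.png", i))) * 255))
      }
    }
    list(x = x, records = records, n = ns)
  })
  structure(c(splits, list(config = config, bank_config = NULL)),
            class = "scene_dataset")
}
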