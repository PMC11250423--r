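# Object bank: exemplars with intrinsic luminance and orientation transforms.

#' Canonical attribute level sets
#'
#' Luminance levels and orientations in their default map order: luminance
#' from dark to bright, orientation up, left, down, right (successive
#' 90-degree counter-clockwise rotations).
#'
#' @return Character vector of level names.
#' @export
luminance_levels <- function() c("low", "medium_low", "medium_high", "high")

#' @rdname luminance_levels
#' @export
orientations <- function() c("up", "left", "down", "right")

#' Mean luminance of an object patch
#'
#' The luminance value of an object is the arithmetic mean over *all* pixels
#' of its patch, explicitly including the zero-valued background pixels inside
#' the patch.
#'
#' @param image Numeric matrix with values in `[0, 255]`.
#' @return A single number in `[0, 255]`.
#' @examples
#' luminance_value(matrix(c(0, 255, 0, 255), 2, 2))
#' @export
luminance_value <- function(image) {
  fail_unless(is.matrix(image) && length(image) > 0, "image must be a non-empty matrix")
  fail_unless(all(is.finite(image)) && min(image) >= 0 && max(image) <= 255,
              "pixel values must lie in [0, 255]")
  mean(image)
}

#' Luminance level of a luminance value
#'
#' Bins a mean luminance into four levels at multiples of 255/8: `low`
#' (< 255/8), `medium_low` (255/8 to < 2*255/8), `medium_high` (2*255/8 to
#' < 3*255/8) and `high` (>= 3*255/8).  Boundaries are closed below and open
#' above.
#'
#' @param value Numeric vector of luminance values in `[0, 255]`.
#' @return Character vector of level labels.
#' @examples
#' luminance_level(c(0, 63.75, 95.625, 255))
#' @export
luminance_level <- function(value) {
  fail_unless(all(is.finite(value)) && all(value >= 0) && all(value <= 255),
              "luminance value must lie in [0, 255]")
  step <- 255 / 8
  lv <- luminance_levels()
  out <- character(length(value))
  out[value < step] <- lv[1]
  out[value >= step & value < 2 * step] <- lv[2]
  out[value >= 2 * step & value < 3 * step] <- lv[3]
  out[value >= 3 * step] <- lv[4]
  out
}

# Rotate a square matrix 90 degrees counter-clockwise.
rot90_ccw <- function(m) {
  t(m)[ncol(m):1, , drop = FALSE]
}

#' Rotate an object patch into a named orientation
#'
#' `up` leaves the patch unchanged; `left`, `down` and `right` apply one, two
#' and three 90-degree counter-clockwise rotations.  Rotation permutes pixels,
#' so the luminance value is unchanged.
#'
#' @param image Square numeric matrix (or an exemplar list with an `$image`
#'   field).
#' @param orientation One of `"up"`, `"left"`, `"down"`, `"right"`.
#' @return The rotated patch (same type as the input).
#' @export
rotate_object <- function(image, orientation) {
  if (is.list(image) && !is.null(image$image)) {
    image$image <- rotate_object(image$image, orientation)
    return(image)
  }
  fail_unless(is.matrix(image) && nrow(image) == ncol(image),
              "object patch must be square")
  k <- match(orientation, orientations())
  fail_unless(!is.na(k), "unknown orientation '%s'", as.character(orientation))
  for (i in seq_len(k - 1)) image <- rot90_ccw(image)
  image
}

#' Configure an object bank
#'
#' @param source `"glyph"` (procedural silhouettes, the default) or
#'   `"fashion_mnist"` (requires IDX files, see `fashion_dir`).
#' @param class_names Identity classes.  The default four classes have
#'   distinct silhouette families; the "tops" set
#'   `c("t-shirt", "pullover", "coat", "shirt")` gives four visually similar
#'   classes used to remove identity/luminance/orientation dependencies.
#' @param n_per_class Number of exemplars per class.
#' @param obj_size Patch side length in pixels.
#' @param glyph_luminance_means,glyph_luminance_sds Per-class mean and SD of
#'   the intrinsic luminance distribution (glyph source only).  Distinct means
#'   create an identity-luminance dependency; equal means remove it.
#' @param glyph_luminance_range Truncation range for sampled luminance
#'   targets, shared by all classes so that equal-mean classes get identical
#'   distributions regardless of silhouette area (upper end must stay within
#'   what the smallest silhouette can render).
#' @param seed Integer seed; banks are rebuildable bit-identically.
#' @param fashion_dir Directory holding Fashion-MNIST
#'   `train-images-idx3-ubyte[.gz]` and `train-labels-idx1-ubyte[.gz]`.
#' @return A `bank_config` list.
#' @export
bank_config <- function(source = c("glyph", "fashion_mnist"),
                        class_names = c("t-shirt", "pant", "shoe", "bag"),
                        n_per_class = 200,
                        obj_size = 28,
                        glyph_luminance_means = NULL,
                        glyph_luminance_sds = NULL,
                        glyph_luminance_range = c(4, 105),
                        seed = 1L,
                        fashion_dir = NULL) {
  source <- match.arg(source)
  fail_unless(n_per_class >= 1, "n_per_class must be >= 1")
  fail_unless(length(class_names) >= 1 && !anyDuplicated(class_names),
              "class_names must be distinct")
  if (source == "glyph") {
    unknown <- setdiff(class_names, glyph_classes())
    fail_unless(length(unknown) == 0, "unknown class name(s): %s",
                paste(unknown, collapse = ", "))
    if (is.null(glyph_luminance_means)) {
      # defaults emulate the intrinsic class luminance structure of the
      # corresponding clothing photographs: dark shoes, mid pants,
      # brighter shirts and bags; tops classes are all bright and similar
      defaults <- c("t-shirt" = 81.0, "pant" = 57.2, "shoe" = 33.6,
                    "bag" = 85.8, "pullover" = 95.9, "coat" = 100.9,
                    "shirt" = 86.9)
      glyph_luminance_means <- unname(defaults[class_names])
    }
    if (is.null(glyph_luminance_sds)) {
      defaults <- c("t-shirt" = 28.6, "pant" = 13.7, "shoe" = 14.9,
                    "bag" = 26.2, "pullover" = 33.2, "coat" = 26.4,
                    "shirt" = 33.3)
      glyph_luminance_sds <- unname(defaults[class_names])
    }
    fail_unless(length(glyph_luminance_means) == length(class_names),
                "glyph_luminance_means must have one entry per class")
    fail_unless(length(glyph_luminance_sds) == length(class_names),
                "glyph_luminance_sds must have one entry per class")
  }
  structure(
    list(source = source, class_names = class_names,
         n_per_class = as.integer(n_per_class), obj_size = as.integer(obj_size),
         glyph_luminance_means = glyph_luminance_means,
         glyph_luminance_sds = glyph_luminance_sds,
         glyph_luminance_range = glyph_luminance_range,
         seed = as.integer(seed), fashion_dir = fashion_dir),
    class = "bank_config"
  )
}

#' Build an object bank
#'
#' Generates (or loads) `n_per_class` exemplars per identity class, labelled
#' with their intrinsic luminance value and level.  Luminance is intrinsic:
#' it is measured from the rendered patch, never equalized afterwards.
#'
#' @param config A [bank_config()].
#' @return An `object_bank`: list with `images` (list of `obj_size` square
#'   matrices, values in `[0, 255]`), `meta` (tibble: `exemplar_id`,
#'   `class_label`, `luminance_value`, `luminance_level`) and the config.
#' @examples
#' bank <- build_bank(bank_config(n_per_class = 5, obj_size = 16, seed = 7))
#' table(bank$meta$class_label)
#' @export
build_bank <- function(config = bank_config()) {
  fail_unless(inherits(config, "bank_config"), "config must come from bank_config()")
  if (config$source == "glyph") {
    bank <- with_seed(config$seed, build_glyph_bank(config))
  } else {
    bank <- with_seed(config$seed, build_fashion_bank(config))
  }
  bank
}

build_glyph_bank <- function(config) {
  n_cls <- length(config$class_names)
  images <- vector("list", n_cls * config$n_per_class)
  cls <- character(length(images))
  id <- 0L
  for (k in seq_len(n_cls)) {
    mu <- config$glyph_luminance_means[k]
    sdv <- config$glyph_luminance_sds[k]
    for (i in seq_len(config$n_per_class)) {
      id <- id + 1L
      rng <- config$glyph_luminance_range
      target <- clamp(rnorm(1, mu, sdv), rng[1], rng[2])
      images[[id]] <- render_glyph(config$class_names[k], config$obj_size, target)
      cls[id] <- config$class_names[k]
    }
  }
  finish_bank(images, cls, config)
}

finish_bank <- function(images, cls, config) {
  lum <- vapply(images, luminance_value, numeric(1))
  meta <- tibble::tibble(
    exemplar_id = seq_along(images),
    class_label = cls,
    luminance_value = lum,
    luminance_level = luminance_level(lum)
  )
  structure(list(images = images, meta = meta, config = config),
            class = "object_bank")
}

#' @export
print.object_bank <- function(x, ...) {
  cat(sprintf("<object_bank> %d exemplars, %d classes (%s), %dpx patches\n",
              nrow(x$meta), length(x$config$class_names),
              paste(x$config$class_names, collapse = ", "),
              x$config$obj_size))
  lum <- stats::aggregate(luminance_value ~ class_label, data = x$meta, FUN = mean)
  cat("mean luminance by class:\n")
  for (i in seq_len(nrow(lum))) {
    cat(sprintf("  %-10s %6.1f\n", lum$class_label[i], lum$luminance_value[i]))
  }
  invisible(x)
}

# ---- Fashion-MNIST adapter -------------------------------------------------

# Read an IDX file (optionally gzipped): returns a list of matrices (images,
# magic 2051) or an integer vector (labels, magic 2049).
read_idx <- function(path) {
  fail_unless(file.exists(path), "IDX file not found: %s", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (magic == 2049L) {
    n <- readBin(con, "integer", 1, size = 4, endian = "big")
    as.integer(readBin(con, "integer", n, size = 1, signed = FALSE))
  } else if (magic == 2051L) {
    dims <- readBin(con, "integer", 3, size = 4, endian = "big")
    n <- dims[1]; h <- dims[2]; w <- dims[3]
    raw <- readBin(con, "integer", n * h * w, size = 1, signed = FALSE)
    lapply(seq_len(n), function(i) {
      block <- raw[((i - 1) * h * w + 1):(i * h * w)]
      matrix(as.numeric(block), h, w, byrow = TRUE) # IDX stores rows first
    })
  } else {
    stop(sprintf("not an IDX file (magic %d): %s", magic, path), call. = FALSE)
  }
}

fashion_label_map <- function() {
  c("t-shirt" = 0L, "pant" = 1L, "pullover" = 2L, "dress" = 3L, "coat" = 4L,
    "sandal" = 5L, "shirt" = 6L, "shoe" = 7L, "bag" = 8L, "ankle-boot" = 9L)
}

# Handle heuristic for bags: a bag with a handle has foreground pixels
# reaching the top rows of its patch (the handle arc), a handleless bag
# does not.
has_top_mass <- function(image, rows = 3, thresh = 2) {
  sum(image[seq_len(rows), ] > 0) >= thresh
}

build_fashion_bank <- function(config) {
  fail_unless(!is.null(config$fashion_dir), "fashion_mnist source needs fashion_dir")
  find1 <- function(stem) {
    for (ext in c("", ".gz")) {
      p <- file.path(config$fashion_dir, paste0(stem, ext))
      if (file.exists(p)) return(p)
    }
    stop(sprintf("missing Fashion-MNIST file '%s[.gz]' in %s", stem,
                 config$fashion_dir), call. = FALSE)
  }
  imgs <- read_idx(find1("train-images-idx3-ubyte"))
  labs <- read_idx(find1("train-labels-idx1-ubyte"))
  fail_unless(length(imgs) == length(labs), "image/label count mismatch")
  lmap <- fashion_label_map()
  unknown <- setdiff(config$class_names, names(lmap))
  fail_unless(length(unknown) == 0, "unknown class name(s): %s",
              paste(unknown, collapse = ", "))
  images <- list(); cls <- character(0)
  for (cn in config$class_names) {
    idx <- which(labs == lmap[[cn]])
    if (cn == "bag") {
      idx <- idx[vapply(imgs[idx], has_top_mass, logical(1))]
    }
    fail_unless(length(idx) >= config$n_per_class,
                "class '%s': only %d exemplars available, %d requested",
                cn, length(idx), config$n_per_class)
    pick <- sample(idx, config$n_per_class)
    images <- c(images, imgs[pick])
    cls <- c(cls, rep(cn, config$n_per_class))
  }
  if (config$obj_size != nrow(images[[1]])) {
    fail_unless(config$obj_size == nrow(images[[1]]),
                "fashion patches are %dpx; set obj_size accordingly",
                nrow(images[[1]]))
  }
  finish_bank(images, cls, config)
}

# ---- Bank persistence ------------------------------------------------------

#' Write / read an object bank on disk
#'
#' Exemplars are stored as 8-bit grayscale PNGs plus a CSV manifest
#' (`exemplar_id`, `class_label`, `luminance_value`, `luminance_level`) and a
#' JSON config sidecar.  `read_bank()` restores a bank that compares equal on
#' images and manifest.
#'
#' @param bank An `object_bank`.
#' @param dir Directory to write into (created if needed).
#' @return `write_bank()` the directory, invisibly; `read_bank()` the bank.
#' @export
write_bank <- function(bank, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(bank$images)) {
    png::writePNG(bank$images[[i]] / 255,
                  file.path(dir, "images", sprintf("ex_%05d.png", i)))
  }
  write.csv(bank$meta, file.path(dir, "manifest.csv"), row.names = FALSE)
  cfg <- bank$config
  cfg$fashion_dir <- NULL
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_bank
#' @export
read_bank <- function(dir) {
  manifest <- file.path(dir, "manifest.csv")
  fail_unless(file.exists(manifest), "no manifest.csv under %s", dir)
  meta <- tibble::as_tibble(read.csv(manifest, stringsAsFactors = FALSE))
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  config <- bank_config(source = cfg$source, class_names = cfg$class_names,
                        n_per_class = cfg$n_per_class, obj_size = cfg$obj_size,
                        glyph_luminance_means = cfg$glyph_luminance_means,
                        glyph_luminance_sds = cfg$glyph_luminance_sds,
                        glyph_luminance_range = cfg$glyph_luminance_range,
                        seed = cfg$seed)
  images <- lapply(meta$exemplar_id, function(i) {
    round(png::readPNG(file.path(dir, "images", sprintf("ex_%05d.png", i))) * 255)
  })
  structure(list(images = images, meta = meta, config = config),
            class = "object_bank")
}
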