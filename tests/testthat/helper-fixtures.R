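# Shared fixtures: tiny banks and hand-built record tables.

tiny_bank <- function(seed = 7, n = 8, tops = FALSE) {
  build_bank(desk_bank_config(tops = tops, n_per_class = n, seed = seed))
}

# Cache the default tiny bank across tests (deterministic given the seed).
the_bank <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- tiny_bank()
    cache
  }
})

default_classes <- function(locations = 1:9) {
  attr_classes(list(class_names = c("t-shirt", "pant", "shoe", "bag")),
               list(allowed_locations = locations))
}

# Hand-built object records (luminance_value chosen mid-level).
make_records <- function(identity, level, orientation, location) {
  lv <- c(low = 16, medium_low = 48, medium_high = 80, high = 120)
  tibble::tibble(
    slot = seq_along(identity),
    exemplar_id = seq_along(identity),
    identity = identity,
    luminance_value = unname(lv[level]),
    luminance_level = level,
    orientation = orientation,
    location = as.integer(location)
  )
}

# A small trained-net fixture config: fast and deterministic.
micro_net_config <- function(max_epochs = 6) {
  net_config(conv_blocks = list(), dense_widths = c(32, 16), dropout = 0.3,
             batch_size = 128, learning_rate = 0.003, max_epochs = max_epochs,
             patience = max_epochs, input_pool = 2, common_dense = c(16))
}

micro_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_dataset(the_bank(),
                                 desk_dataset_config(n_images = 180, seed = 5))
    }
    cache
  }
})

# Minimal IDX (Fashion-MNIST dialect) writer for synthetic adapter fixtures.
write_idx_images <- function(path, images) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(2051L, length(images), nrow(images[[1]]), ncol(images[[1]])),
           con, size = 4, endian = "big")
  for (im in images) {
    writeBin(as.integer(t(im)), con, size = 1, endian = "big")
  }
}

write_idx_labels <- function(path, labels) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(2049L, length(labels)), con, size = 4, endian = "big")
  writeBin(as.integer(labels), con, size = 1, endian = "big")
}
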