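# Constraint maps: order a scene's objects by one attribute and encode
# per-slot one-hot targets for the task attribute(s).

map_names <- function() c("location", "identity", "luminance", "orientation")

#' Attribute class sets for a dataset variant
#'
#' The class set of each attribute, in its default map order: identities in
#' the configured class order, luminance levels dark to bright, orientations
#' up/left/down/right, locations in raster (row-major) order restricted to
#' the variant's allowed set.
#'
#' @param bank_config A [bank_config()] (or any list with `class_names`).
#' @param dataset_config A [dataset_config()] (or any list with
#'   `allowed_locations`); defaults to all nine locations.
#' @return Named list `identity`, `luminance`, `orientation`, `location`.
#' @export
attr_classes <- function(bank_config, dataset_config = NULL) {
  locs <- if (is.null(dataset_config)) 1:9 else dataset_config$allowed_locations
  list(
    identity = bank_config$class_names,
    luminance = luminance_levels(),
    orientation = orientations(),
    location = as.integer(locs)
  )
}

#' Sortable map key of object records
#'
#' Returns, for every record, its integer rank under the named constraint
#' map: locations rank by grid row then column (equivalently by their
#' raster-order number), identities by the configured class order, luminance
#' levels dark to bright, orientations up, left, down, right.  Any consistent
#' order would do; these defaults follow `attr_classes()`.
#'
#' @param records Tibble of object records (columns `identity`,
#'   `luminance_level`, `orientation`, `location`).
#' @param map_name One of `"location"`, `"identity"`, `"luminance"`,
#'   `"orientation"`.
#' @param classes An [attr_classes()] list giving the class orders.
#' @return Integer vector of keys (ties possible for every map but location).
#' @export
map_key <- function(records, map_name, classes) {
  fail_unless(map_name %in% map_names(), "unknown map '%s'", as.character(map_name))
  key <- switch(map_name,
    location = match(records$location, sort(classes$location)),
    identity = match(records$identity, classes$identity),
    luminance = match(records$luminance_level, classes$luminance),
    orientation = match(records$orientation, classes$orientation)
  )
  fail_unless(!anyNA(key), "record attribute outside the configured class set")
  key
}

#' Order a scene's objects under a constraint map
#'
#' Objects are sorted by their [map_key()]; objects with equal keys form tie
#' groups.  Under `tie_policy = "canonical"` ties are broken by location
#' (giving deterministic supervised targets); `"free"` keeps the same
#' canonical permutation but marks tie groups as permutation-equivalent for
#' scoring.
#'
#' @inheritParams map_key
#' @param tie_policy `"canonical"` or `"free"`.
#' @return A `map_ordering`: list with `map_name`, `permutation` (slot ->
#'   record index), `tie_groups` (list of slot vectors with equal keys),
#'   `keys` (per record) and `tie_policy`.
#' @export
order_objects <- function(records, map_name, classes,
                          tie_policy = c("canonical", "free")) {
  tie_policy <- match.arg(tie_policy)
  fail_unless(nrow(records) >= 1, "need at least one record")
  keys <- map_key(records, map_name, classes)
  loc_key <- match(records$location, sort(classes$location))
  perm <- order(keys, loc_key)
  sorted_keys <- keys[perm]
  groups <- split(seq_along(perm), sorted_keys)
  tie_groups <- unname(groups[vapply(groups, length, integer(1)) > 1])
  structure(
    list(map_name = map_name, permutation = perm, tie_groups = tie_groups,
         keys = keys, tie_policy = tie_policy),
    class = "map_ordering"
  )
}

#' One-hot slot targets for a task under a constraint map
#'
#' Orders the objects with [order_objects()] (canonical tie-break) and
#' encodes, per output slot and per task attribute, a one-hot vector over
#' that attribute's class set.  Both attributes of a two-attribute task share
#' the single ordering.
#'
#' @inheritParams map_key
#' @param task_attributes One or two of `"identity"`, `"luminance"`,
#'   `"orientation"`, `"location"`.
#' @return A `target_encoding`: list with `ordering`, `task_attributes`,
#'   `class_idx` (named list of per-slot class indices) and `onehot` (named
#'   list of `n_objects x n_classes` matrices).
#' @export
encode_targets <- function(records, task_attributes, map_name, classes) {
  fail_unless(length(task_attributes) >= 1 && length(task_attributes) <= 2,
              "task_attributes must name one or two attributes")
  fail_unless(all(task_attributes %in% map_names()), "unknown task attribute")
  ordering <- order_objects(records, map_name, classes, "canonical")
  ordered <- records[ordering$permutation, ]
  enc_one <- function(attr) {
    idx <- switch(attr,
      identity = match(ordered$identity, classes$identity),
      luminance = match(ordered$luminance_level, classes$luminance),
      orientation = match(ordered$orientation, classes$orientation),
      location = match(ordered$location, sort(classes$location))
    )
    fail_unless(!anyNA(idx), "attribute class not in configured class set")
    idx
  }
  class_idx <- lapply(setNames(task_attributes, task_attributes), enc_one)
  onehot <- lapply(setNames(task_attributes, task_attributes), function(attr) {
    nc <- length(classes[[attr]])
    m <- matrix(0, nrow(records), nc)
    m[cbind(seq_len(nrow(records)), class_idx[[attr]])] <- 1
    m
  })
  structure(
    list(ordering = ordering, task_attributes = task_attributes,
         class_idx = class_idx, onehot = onehot),
    class = "target_encoding"
  )
}

# All permutations of 1..n (n small), as integer vectors.
all_perms <- function(n) {
  n <- as.integer(n)
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1]] <- append(p, n, after = k - 1L)
    }
  }
  out
}

#' Score predicted slot classifications against a target encoding
#'
#' `mode = "per_slot"` (the default) is the fraction of output heads whose
#' argmax matches the target class; `"per_image"` scores 1 only if every head
#' is correct.  With `tie_policy = "free"`, slots inside a tie group of the
#' target ordering may be reported in any order: the score uses the best
#' permutation of the target slots within each group, jointly over the task
#' attributes.
#'
#' @param predicted Named list (one entry per task attribute) of
#'   `n_objects x n_classes` score matrices.
#' @param truth A [encode_targets()] result.
#' @param mode `"per_slot"` or `"per_image"`.
#' @param tie_policy `"canonical"` or `"free"`.
#' @return Accuracy in `[0, 1]`.
#' @export
score_predictions <- function(predicted, truth,
                              mode = c("per_slot", "per_image"),
                              tie_policy = c("canonical", "free")) {
  mode <- match.arg(mode)
  tie_policy <- match.arg(tie_policy)
  attrs <- truth$task_attributes
  fail_unless(all(attrs %in% names(predicted)),
              "predictions missing task attribute scores")
  n_slots <- length(truth$class_idx[[1]])
  pred_cls <- lapply(attrs, function(a) {
    p <- predicted[[a]]
    fail_unless(is.matrix(p) && nrow(p) == n_slots &&
                  ncol(p) == ncol(truth$onehot[[a]]),
                "prediction shape mismatch for '%s'", a)
    max.col(p, ties.method = "first")
  })
  names(pred_cls) <- attrs
  # correct[s, a] under a given slot->slot assignment of targets
  correct_for <- function(target_slot_of) {
    vapply(attrs, function(a) {
      pred_cls[[a]] == truth$class_idx[[a]][target_slot_of]
    }, logical(n_slots))
  }
  assign0 <- seq_len(n_slots)
  corr <- correct_for(assign0)
  if (tie_policy == "free" && length(truth$ordering$tie_groups) > 0) {
    for (g in truth$ordering$tie_groups) {
      best <- corr
      for (p in all_perms(length(g))) {
        a2 <- assign0
        a2[g] <- g[unlist(p)]
        cand <- correct_for(a2)
        if (sum(cand[g, ]) > sum(best[g, ])) best[g, ] <- cand[g, ]
      }
      corr <- best
    }
  }
  if (mode == "per_slot") mean(corr) else as.numeric(all(corr))
}
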