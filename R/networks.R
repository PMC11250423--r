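# Pathway networks and the frozen-trunk two-pathway combination.

# Integer class-index targets for every scene of a split, slots ordered by
# the constraint map.  Columns: attr1 slots 1..n, then attr2 slots 1..n.
split_targets <- function(split, task_attributes, map_name, classes) {
  recs <- split$records
  n_obj <- max(recs$slot)
  ids <- unique(recs$scene_id)
  Y <- matrix(0L, length(ids), n_obj * length(task_attributes))
  rows_of <- split(seq_len(nrow(recs)), recs$scene_id)
  for (i in seq_along(ids)) {
    enc <- encode_targets(recs[rows_of[[as.character(ids[i])]], ],
                          task_attributes, map_name, classes)
    Y[i, ] <- unlist(enc$class_idx, use.names = FALSE)
  }
  Y
}

head_sizes_for <- function(task_attributes, n_objects, classes) {
  unlist(lapply(task_attributes, function(a) {
    rep(length(classes[[a]]), n_objects)
  }))
}

#' Train a visual pathway network
#'
#' Trains one pathway to report a single attribute of every object in each
#' scene, output slots ordered by the constraint map.  Training uses Adam
#' with per-head cross-entropy, dropout on the dense layers, and early
#' stopping on validation per-slot accuracy with best-weight restoration.
#'
#' @param net A [build_pathway()] network (or `NULL` to build one matching
#'   the dataset and task).
#' @param dataset A [generate_dataset()] result with canvases.
#' @param task_attribute Attribute the pathway reports.
#' @param map_name Constraint map ordering the output slots.
#' @param config A [net_config()].
#' @param seed Seed for initialization, shuffling and dropout.
#' @param verbose Print per-epoch progress.
#' @return A `trained_pathway`: the fitted net plus task, map, class sets,
#'   training history, best validation accuracy and test accuracy (per-slot).
#' @export
train_pathway <- function(net = NULL, dataset, task_attribute, map_name,
                          config = net_config(), seed = 1L, verbose = FALSE) {
  classes <- attr_classes(dataset$bank_config, dataset$config)
  n_obj <- dataset$config$n_objects
  if (is.null(net)) {
    net <- build_pathway(config, n_obj, length(classes[[task_attribute]]),
                         rep(dataset$config$canvas_size, 2), seed = seed)
  }
  fail_unless(identical(sum(net$head_sizes),
                        as.integer(n_obj * length(classes[[task_attribute]]))),
              "network heads do not match task '%s'", task_attribute)
  Ytr <- split_targets(dataset$train, task_attribute, map_name, classes)
  Yva <- split_targets(dataset$val, task_attribute, map_name, classes)
  Yte <- split_targets(dataset$test, task_attribute, map_name, classes)
  fit <- with_seed(seed, fit_net(net, dataset$train$x / 255, Ytr,
                                 dataset$val$x / 255, Yva, verbose = verbose))
  test_scores <- net_predict(fit$net, dataset$test$x / 255)
  structure(
    list(net = fit$net, task_attribute = task_attribute, map_name = map_name,
         classes = classes, history = fit$history,
         best_val_accuracy = fit$best_val_accuracy,
         test_accuracy = heads_accuracy(test_scores, Yte, fit$net$head_sizes),
         seed = seed),
    class = "trained_pathway"
  )
}

#' @export
print.trained_pathway <- function(x, ...) {
  cat(sprintf("<trained_pathway> task %s, %s map: val %.3f, test %.3f (%d epochs)\n",
              x$task_attribute, x$map_name, x$best_val_accuracy,
              x$test_accuracy, nrow(x$history)))
  invisible(x)
}

# Trunk activations: forward through everything except the output heads.
net_features <- function(net, X, batch_size = 1024L) {
  stop_at <- length(net$layers) - 1L
  N <- nrow(X)
  out <- NULL
  for (start in seq(1, N, by = batch_size)) {
    idx <- start:min(N, start + batch_size - 1)
    fwd <- nn_forward(net$layers, X[idx, , drop = FALSE], net$head_sizes,
                      stop_at = stop_at)
    out <- rbind(out, fwd$out)
  }
  out
}

trunk_layers <- function(net) net$layers[-length(net$layers)]

#' Combine two trained pathways into a two-pathway network
#'
#' The two pre-trained pathways (excluding their output heads, weights
#' frozen) become the two trunks; their final trunk layers are concatenated
#' and read out by trainable common dense layers with one softmax head per
#' (attribute, slot).  Both pathways must have been trained under the same
#' constraint map, which the combined network inherits.
#'
#' @param pathway_a,pathway_b `trained_pathway` objects sharing a map.
#' @param config A [net_config()]; `common_dense` gives the trainable layer
#'   widths.
#' @return A `two_pathway_net` (untrained common layers).
#' @export
build_two_pathways <- function(pathway_a, pathway_b, config = net_config()) {
  fail_unless(inherits(pathway_a, "trained_pathway") &&
                inherits(pathway_b, "trained_pathway"),
              "both pathways must be trained_pathway objects")
  fail_unless(identical(pathway_a$map_name, pathway_b$map_name),
              "pathways were trained under different maps ('%s' vs '%s'); the constraint map must be shared",
              pathway_a$map_name, pathway_b$map_name)
  structure(
    list(pathway_a = pathway_a, pathway_b = pathway_b,
         map_name = pathway_a$map_name, config = config,
         trunk_snapshot = list(a = trunk_layers(pathway_a$net),
                               b = trunk_layers(pathway_b$net)),
         common = NULL),
    class = "two_pathway_net"
  )
}

#' Verify that the two-pathway trunks are still frozen
#'
#' @param tp A `two_pathway_net`.
#' @return `TRUE` if both trunks are bit-identical to their pre-training
#'   snapshot.
#' @export
trunks_frozen <- function(tp) {
  identical(trunk_layers(tp$pathway_a$net), tp$trunk_snapshot$a) &&
    identical(trunk_layers(tp$pathway_b$net), tp$trunk_snapshot$b)
}

#' Train the common layers of a two-pathway network
#'
#' Only the common dense layers and the `2 x n_objects` softmax heads are
#' trainable; the pathway trunks stay bit-identical to their pre-trained
#' weights (their activations are computed once per split).  Accuracy is
#' reported per-slot over all heads of both attributes.
#'
#' @param tp A [build_two_pathways()] network.
#' @param dataset The dataset (same variant the pathways were trained on).
#' @param task_pair Character vector of the two attributes to report.
#' @param map_name Constraint map; must equal the pathways' shared map.
#' @param seed Seed for the trainable layers.
#' @param verbose Print per-epoch progress.
#' @return The `two_pathway_net` with fitted common layers, plus
#'   `test_accuracy`, `best_val_accuracy` and `history`.
#' @export
train_two_pathways <- function(tp, dataset, task_pair, map_name = tp$map_name,
                               seed = 1L, verbose = FALSE) {
  fail_unless(inherits(tp, "two_pathway_net"), "tp must come from build_two_pathways()")
  fail_unless(identical(map_name, tp$map_name),
              "map '%s' does not match the pathways' shared map '%s'",
              map_name, tp$map_name)
  fail_unless(length(task_pair) == 2, "task_pair must name two attributes")
  classes <- attr_classes(dataset$bank_config, dataset$config)
  n_obj <- dataset$config$n_objects
  feats <- lapply(c(train = "train", val = "val", test = "test"), function(sp) {
    X <- dataset[[sp]]$x / 255
    cbind(net_features(tp$pathway_a$net, X), net_features(tp$pathway_b$net, X))
  })
  Ytr <- split_targets(dataset$train, task_pair, map_name, classes)
  Yva <- split_targets(dataset$val, task_pair, map_name, classes)
  Yte <- split_targets(dataset$test, task_pair, map_name, classes)
  head_sizes <- head_sizes_for(task_pair, n_obj, classes)
  cfg <- tp$config
  cfg$input_pool <- 1L
  cfg$conv_blocks <- list()
  cfg$dense_widths <- cfg$common_dense
  common <- with_seed(seed, {
    layers <- build_layers(cfg, c(1L, ncol(feats$train)), head_sizes)
    structure(list(input_shape = c(1L, ncol(feats$train)), layers = layers,
                   head_sizes = head_sizes, config = cfg),
              class = "pathway_net")
  })
  fit <- with_seed(seed + 1L, fit_net(common, feats$train, Ytr, feats$val, Yva,
                                      verbose = verbose))
  test_scores <- net_predict(fit$net, feats$test)
  tp$common <- fit$net
  tp$task_pair <- task_pair
  tp$history <- fit$history
  tp$best_val_accuracy <- fit$best_val_accuracy
  tp$test_accuracy <- heads_accuracy(test_scores, Yte, head_sizes)
  fail_unless(trunks_frozen(tp), "internal error: trunk weights changed during training")
  tp
}

#' @export
print.two_pathway_net <- function(x, ...) {
  cat(sprintf("<two_pathway_net> pathways (%s, %s), %s map",
              x$pathway_a$task_attribute, x$pathway_b$task_attribute, x$map_name))
  if (!is.null(x$common)) {
    cat(sprintf(": tasks (%s), test %.3f", paste(x$task_pair, collapse = ", "),
                x$test_accuracy))
  }
  cat("\n")
  invisible(x)
}
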