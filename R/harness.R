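# Factorial experiment harness: variants x maps x tasks x repetitions.

#' Attribute pairs in table order
#'
#' The six unordered attribute pairs, enumerated as the two-pathway result
#' tables list them.
#'
#' @return List of length-2 character vectors.
#' @export
task_pairs <- function() {
  list(c("identity", "luminance"), c("orientation", "location"),
       c("identity", "orientation"), c("identity", "location"),
       c("luminance", "orientation"), c("luminance", "location"))
}

pair_label <- function(pair) paste(pair, collapse = "+")

#' Specify an experiment grid
#'
#' @param variants Dataset variants to run.
#' @param tasks Single-attribute pathway tasks.
#' @param pairs Attribute pairs for the two-pathway networks.
#' @param maps Constraint maps.
#' @param reps Repetitions (independently seeded training runs) per cell.
#' @param base_seed Base seed from which every cell's seed is derived via
#'   [seed_for()].
#' @return A `grid_spec` list.
#' @export
grid_spec <- function(variants = "original",
                      tasks = map_names(),
                      pairs = task_pairs(),
                      maps = map_names(),
                      reps = 3,
                      base_seed = 1L) {
  structure(
    list(variants = variants, tasks = tasks, pairs = pairs, maps = maps,
         reps = as.integer(reps), base_seed = as.integer(base_seed)),
    class = "grid_spec"
  )
}

record_row <- function(network, task, map, variant, rep, seed, accuracy,
                       epochs, elapsed, status = "ok") {
  tibble::tibble(network = network, task = task, map = map, variant = variant,
                 rep = rep, seed = seed, accuracy = accuracy,
                 epochs = epochs, elapsed = elapsed, status = status)
}

ledger_read <- function(path) {
  if (is.null(path) || !file.exists(path)) return(NULL)
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

ledger_append <- function(path, row) {
  if (is.null(path)) return(invisible(NULL))
  write.table(row, path, sep = ",", row.names = FALSE,
              col.names = !file.exists(path), append = file.exists(path))
  invisible(NULL)
}

ledger_has <- function(ledger, network, task, map, variant, rep) {
  if (is.null(ledger) || nrow(ledger) == 0) return(FALSE)
  any(ledger$network == network & ledger$task == task & ledger$map == map &
        ledger$variant == variant & ledger$rep == rep & ledger$status == "ok")
}

#' Run the factorial experiment grid
#'
#' For every (variant, map, repetition) cell: generate the variant's dataset
#' (seeded from the base seed and variant; the repetition varies only the
#' training run), train the four single-attribute pathway networks, then
#' reuse their frozen trunks for every requested attribute pair.  Each
#' completed measurement yields one accuracy record.  With a `ledger_path`,
#' records are appended to a CSV as they complete and already-completed
#' cells are skipped on re-runs; a failed cell is recorded with status
#' `"failed"` and does not abort the grid.
#'
#' @param bank An `object_bank`.
#' @param grid A [grid_spec()].
#' @param net_cfg A [net_config()].
#' @param n_images,canvas_size Dataset size parameters shared by all
#'   variants.
#' @param ledger_path Optional CSV path for resumable record keeping.
#' @param verbose Print one line per completed cell.
#' @return Tibble of accuracy records (`network`, `task`, `map`, `variant`,
#'   `rep`, `seed`, `accuracy`, `epochs`, `elapsed`, `status`).
#' @export
run_grid <- function(bank, grid, net_cfg = net_config(),
                     n_images = 6000, canvas_size = 140,
                     ledger_path = NULL, verbose = FALSE) {
  ledger <- ledger_read(ledger_path)
  records <- list()
  note <- function(row) {
    records[[length(records) + 1]] <<- row
    ledger_append(ledger_path, row)
    if (verbose) {
      message(sprintf("%-12s %-22s %-12s %-22s rep %d  acc %.3f",
                      row$variant, row$task, row$map, row$network, row$rep,
                      row$accuracy))
    }
  }
  pathway_tasks <- union(grid$tasks, unlist(grid$pairs))
  for (variant in grid$variants) {
    dcfg <- dataset_config(variant = variant, n_images = n_images,
                           canvas_size = canvas_size,
                           seed = seed_for(grid$base_seed, "dataset", variant))
    dataset <- generate_dataset(bank, dcfg)
    for (map in grid$maps) {
      for (rep in seq_len(grid$reps)) {
        trained <- list()
        pairs_todo <- Filter(function(p) {
          !ledger_has(ledger, "two_pathway", pair_label(p), map, variant, rep)
        }, grid$pairs)
        for (task in pathway_tasks) {
          need_for_pair <- any(vapply(pairs_todo, function(p) task %in% p,
                                      logical(1)))
          done <- ledger_has(ledger, "pathway", task, map, variant, rep)
          if (done && !need_for_pair) next
          seed <- seed_for(grid$base_seed, variant, task, map, rep)
          t0 <- proc.time()[["elapsed"]]
          pw <- tryCatch(
            train_pathway(NULL, dataset, task, map, net_cfg, seed = seed),
            error = function(e) e
          )
          if (inherits(pw, "error")) {
            note(record_row("pathway", task, map, variant, rep, seed, NA_real_,
                            NA_integer_, NA_real_, paste("failed:", conditionMessage(pw))))
            next
          }
          trained[[task]] <- pw
          if (!done && task %in% grid$tasks) {
            note(record_row("pathway", task, map, variant, rep, seed,
                            pw$test_accuracy, nrow(pw$history),
                            proc.time()[["elapsed"]] - t0))
          }
        }
        for (pair in pairs_todo) {
          if (!all(pair %in% names(trained))) next
          seed <- seed_for(grid$base_seed, variant, pair_label(pair), map, rep)
          t0 <- proc.time()[["elapsed"]]
          tp <- tryCatch({
            tp0 <- build_two_pathways(trained[[pair[1]]], trained[[pair[2]]],
                                      net_cfg)
            train_two_pathways(tp0, dataset, pair, map, seed = seed)
          }, error = function(e) e)
          if (inherits(tp, "error")) {
            note(record_row("two_pathway", pair_label(pair), map, variant, rep,
                            seed, NA_real_, NA_integer_, NA_real_,
                            paste("failed:", conditionMessage(tp))))
            next
          }
          note(record_row("two_pathway", pair_label(pair), map, variant, rep,
                          seed, tp$test_accuracy, nrow(tp$history),
                          proc.time()[["elapsed"]] - t0))
        }
      }
    }
  }
  dplyr::bind_rows(records)
}

# ---- desk-scale presets ----------------------------------------------------

#' Desk-scale presets
#'
#' A reduced problem size for single-CPU runs: a 56 px canvas with 16 px
#' glyphs, 60 exemplars per class, 1500 scenes, and a dense trunk on a
#' 2x-average-pooled input.  `tops = TRUE` selects the four "tops" classes
#' with equal intrinsic luminance distributions (attributes independent);
#' `tops = FALSE` keeps the four distinct classes with class-dependent
#' luminance.
#'
#' @param tops Use the independent-attribute tops bank.
#' @param n_per_class Exemplars per class.
#' @param seed Bank seed.
#' @return `desk_bank_config()`: a [bank_config()]; `desk_net_config()`: a
#'   [net_config()]; `desk_dataset_config()`: a [dataset_config()].
#' @export
desk_bank_config <- function(tops = FALSE, n_per_class = 60, seed = 1L) {
  if (tops) {
    bank_config(class_names = c("t-shirt", "pullover", "coat", "shirt"),
                n_per_class = n_per_class, obj_size = 16,
                glyph_luminance_means = rep(88, 4),
                glyph_luminance_sds = rep(30, 4), seed = seed)
  } else {
    bank_config(class_names = c("t-shirt", "pant", "shoe", "bag"),
                n_per_class = n_per_class, obj_size = 16, seed = seed)
  }
}

#' @rdname desk_bank_config
#' @export
desk_net_config <- function() {
  net_config(conv_blocks = list(), dense_widths = c(256, 128),
             dropout = 0.30, batch_size = 256, learning_rate = 0.003,
             max_epochs = 120, patience = 15, input_pool = 2,
             common_dense = c(64))
}

#' @rdname desk_bank_config
#' @param variant Dataset variant.
#' @param n_images Number of scenes.
#' @export
desk_dataset_config <- function(variant = "original", n_images = 1500,
                                seed = 1L) {
  dataset_config(variant = variant, n_images = n_images, canvas_size = 56,
                 seed = seed)
}
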