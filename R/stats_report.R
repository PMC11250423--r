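# Statistical summaries: mean +/- SD tables, Welch tests, percentage gains.

#' Summarize accuracy records into mean +/- SD cells
#'
#' Per (variant, network, task, map): the mean and SD of test accuracy over
#' repetitions, as percentages, plus a `"83.1 ± 2.9"`-style label
#' (one decimal, mirroring the experiment tables).
#'
#' @param records Accuracy records from [run_grid()].
#' @return Tibble with `variant`, `network`, `task`, `map`, `n_reps`,
#'   `mean_pct`, `sd_pct`, `cell`.
#' @export
summarize_cells <- function(records) {
  ok <- records[records$status == "ok" & !is.na(records$accuracy), ]
  fail_unless(nrow(ok) >= 1, "no completed records to summarize")
  out <- ok |>
    dplyr::group_by(.data$variant, .data$network, .data$task, .data$map) |>
    dplyr::summarise(
      n_reps = dplyr::n(),
      mean_pct = 100 * mean(.data$accuracy),
      sd_pct = 100 * stats::sd(.data$accuracy),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      sd_pct = ifelse(is.na(.data$sd_pct), 0, .data$sd_pct),
      cell = sprintf("%.1f ± %.1f", .data$mean_pct, .data$sd_pct)
    )
  out
}

#' Welch's two-sample t-test
#'
#' Unequal-variance two-sample t statistic with Welch-Satterthwaite degrees
#' of freedom and a two-sided p-value.  Degenerate inputs (both variances
#' zero) get `p = 1` when the means are equal and are flagged otherwise.
#'
#' @param a,b Numeric samples (each of length >= 2).
#' @return List with `t`, `df`, `p`, `significant` (p < 0.05) and
#'   `degenerate`.
#' @examples
#' welch_test(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6))
#' @export
welch_test <- function(a, b) {
  fail_unless(length(a) >= 2 && length(b) >= 2,
              "each sample needs at least 2 observations")
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = na + nb - 2, p = 1, significant = FALSE,
                  degenerate = TRUE))
    }
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = na + nb - 2, p = 0,
                significant = TRUE, degenerate = TRUE))
  }
  se2 <- va / na + vb / nb
  tstat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  list(t = tstat, df = df, p = p, significant = p < 0.05, degenerate = FALSE)
}

#' Percentage gain of the location map over another map
#'
#' `(location_acc - other_acc) / other_acc * 100`: the relative accuracy
#' advantage, in percent, of constraining the binding problem with the
#' location map instead of another map.
#'
#' @param location_acc Mean accuracy under the location map.
#' @param other_acc Mean accuracy under the other map (> 0).
#' @return Gain in percent (vectorized).
#' @examples
#' percentage_gain(44.8, 31.9)
#' @export
percentage_gain <- function(location_acc, other_acc) {
  fail_unless(all(other_acc > 0), "other-map accuracy must be > 0")
  (location_acc - other_acc) / other_acc * 100
}

#' Location-map comparisons for the two-pathway cells
#'
#' For every (variant, task pair): Welch tests of the location-map
#' repetitions against each other map's repetitions, and the percentage gain
#' of the location-map mean over the other map's mean.
#'
#' @param records Accuracy records from [run_grid()].
#' @return Tibble with `variant`, `task`, `other_map`, `t`, `df`, `p`,
#'   `significant`, `gain_pct`.
#' @export
compare_to_location_map <- function(records) {
  ok <- records[records$status == "ok" & records$network == "two_pathway", ]
  fail_unless(nrow(ok) >= 1, "no two-pathway records")
  cells <- unique(ok[, c("variant", "task")])
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    sub <- ok[ok$variant == cells$variant[i] & ok$task == cells$task[i], ]
    loc <- sub$accuracy[sub$map == "location"]
    for (m in setdiff(unique(sub$map), "location")) {
      other <- sub$accuracy[sub$map == m]
      if (length(loc) < 2 || length(other) < 2) next
      wt <- welch_test(loc, other)
      rows[[length(rows) + 1]] <- tibble::tibble(
        variant = cells$variant[i], task = cells$task[i], other_map = m,
        t = wt$t, df = wt$df, p = wt$p, significant = wt$significant,
        gain_pct = percentage_gain(mean(loc), mean(other))
      )
    }
  }
  dplyr::bind_rows(rows)
}

fig_task_label <- function(task) {
  shorten <- c(identity = "I", luminance = "LU", orientation = "O",
               location = "LO")
  vapply(strsplit(task, "+", fixed = TRUE), function(p) {
    paste(shorten[p], collapse = "_")
  }, character(1))
}

#' Write a report of an experiment grid
#'
#' Per variant: a pathways table (`<variant>_pathways.csv`, tasks x maps) and
#' a two-pathway pairs table (`<variant>_pairs.csv`), plus Welch
#' location-map comparisons with percentage gains (`comparisons.csv`) and a
#' gain bar chart per other map (`gains.png`, task labels I_LU, O_LO, I_O,
#' I_LO, LU_O, LU_LO).
#'
#' @param records Accuracy records from [run_grid()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list of files written.
#' @export
render_report <- function(records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  if (nrow(records) == 0 || all(records$status != "ok")) {
    warning("no completed records; writing empty report", call. = FALSE)
    f <- file.path(dir, "comparisons.csv")
    write.csv(data.frame(), f, row.names = FALSE)
    return(invisible(f))
  }
  summary <- summarize_cells(records)
  wide <- function(sub) {
    maps <- map_names()
    tasks <- unique(sub$task)
    m <- matrix("", length(tasks), length(maps),
                dimnames = list(tasks, maps))
    for (i in seq_len(nrow(sub))) m[sub$task[i], sub$map[i]] <- sub$cell[i]
    data.frame(task = tasks, m, check.names = FALSE)
  }
  for (v in unique(summary$variant)) {
    for (kind in c("pathway", "two_pathway")) {
      sub <- summary[summary$variant == v & summary$network == kind, ]
      if (nrow(sub) == 0) next
      f <- file.path(dir, sprintf("%s_%s.csv", v,
                                  if (kind == "pathway") "pathways" else "pairs"))
      write.csv(wide(sub), f, row.names = FALSE)
      files <- c(files, f)
    }
  }
  comps <- compare_to_location_map(records)
  f <- file.path(dir, "comparisons.csv")
  write.csv(comps, f, row.names = FALSE)
  files <- c(files, f)
  if (nrow(comps) > 0) {
    comps$task_label <- factor(fig_task_label(comps$task),
                               levels = unique(fig_task_label(comps$task)))
    plt <- ggplot2::ggplot(comps,
                           ggplot2::aes(x = .data$task_label, y = .data$gain_pct)) +
      ggplot2::geom_col(fill = "grey30") +
      ggplot2::geom_hline(yintercept = 0) +
      ggplot2::facet_grid(variant ~ other_map) +
      ggplot2::labs(x = "task (attribute pair)",
                    y = "accuracy gain of location map (%)") +
      ggplot2::theme_minimal()
    f <- file.path(dir, "gains.png")
    ok <- tryCatch({
      grDevices::png(f, width = 1600, height = 500 + 300 *
                       length(unique(comps$variant)), res = 150,
                     type = if (capabilities("cairo")) "cairo" else "Xlib")
      print(plt)
      grDevices::dev.off()
      TRUE
    }, error = function(e) FALSE)
    if (ok) files <- c(files, f)
  }
  invisible(files)
}
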