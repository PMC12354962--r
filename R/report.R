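# Reporting: every number shown in a figure is also written to CSV; the
# CSVs are the authoritative output, figures are best-effort rendering.

#' Summarize panel evaluations into one row each
#'
#' For a list of evaluations (classification strategies), rows keep the
#' input order; for a `subset_map`, rows are ranked by mean test
#' balanced accuracy descending with ties broken by smaller subset size
#' and then lexicographic subset label.
#'
#' @param evaluations A list of `panel_eval` objects (optionally named)
#'   or a `subset_map`.
#' @return A data frame with one row per evaluation: label, means and
#'   sample standard deviations of train/test balanced accuracy and test
#'   misclassifications, and `n_sweeps`. Empty input gives a zero-row
#'   frame.
#' @export
summarize_evaluations <- function(evaluations) {
  is_map <- inherits(evaluations, "subset_map")
  empty <- data.frame(strategy_or_subset = character(0),
                      mean_train_balanced_accuracy = numeric(0),
                      std_train_balanced_accuracy = numeric(0),
                      mean_test_balanced_accuracy = numeric(0),
                      std_test_balanced_accuracy = numeric(0),
                      mean_test_misclassified = numeric(0),
                      std_test_misclassified = numeric(0),
                      n_sweeps = integer(0))
  if (length(evaluations) == 0) return(empty)
  labels <- names(evaluations)
  if (is.null(labels) || any(!nzchar(labels))) {
    labels <- vapply(evaluations, function(ev) {
      if (identical(ev$mode, "RANDOM")) paste0("RANDOM(", ev$gene_names, ")")
      else paste(ev$gene_names, collapse = "+")
    }, character(1))
  }
  rows <- lapply(seq_along(evaluations), function(i) {
    sm <- summary(evaluations[[i]])
    data.frame(strategy_or_subset = labels[i],
               mean_train_balanced_accuracy = sm$mean_train_balanced_accuracy,
               std_train_balanced_accuracy = sm$std_train_balanced_accuracy,
               mean_test_balanced_accuracy = sm$mean_test_balanced_accuracy,
               std_test_balanced_accuracy = sm$std_test_balanced_accuracy,
               mean_test_misclassified = sm$mean_test_misclassified,
               std_test_misclassified = sm$std_test_misclassified,
               n_sweeps = sm$n_sweeps)
  })
  out <- do.call(rbind, rows)
  if (is_map) {
    size <- vapply(strsplit(out$strategy_or_subset, "+", fixed = TRUE),
                   length, integer(1))
    out <- out[order(-out$mean_test_balanced_accuracy, size,
                     out$strategy_or_subset), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

sweep_frame <- function(evaluations, labels = NULL) {
  if (is.null(labels)) labels <- summarize_evaluations(evaluations)$strategy_or_subset
  do.call(rbind, lapply(seq_along(evaluations), function(i) {
    s <- evaluations[[i]]$sweeps
    s$strategy <- labels[i]
    s
  }))
}

save_plot <- function(p, path) {
  ggplot2::ggsave(path, p, width = 8, height = 5, dpi = 600)
}

#' Plot and export per-strategy classification results
#'
#' Produces the accuracy-across-sweeps line plot (solid lines: test;
#' dashed: train), a horizontal misclassification bar chart with error
#' bars, and a CSV summary whose values equal
#' [summarize_evaluations()] exactly. Figures are written as PNG at 600
#' dpi.
#'
#' @param evaluations List of `panel_eval` objects.
#' @param output_folder Writable output folder (created if absent).
#' @param save_csv,save_png Toggles for the CSV and image outputs.
#' @param prefix Filename prefix (default `"plot_results"`).
#' @return Character vector of files written, invisibly.
#' @export
plot_results <- function(evaluations, output_folder, save_csv = TRUE,
                         save_png = TRUE, prefix = "plot_results") {
  dir.create(output_folder, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(output_folder)) stop("cannot create folder ", output_folder, call. = FALSE)
  summary_df <- summarize_evaluations(evaluations)
  files <- character(0)
  if (save_csv) {
    csv <- file.path(output_folder, paste0(prefix, "_summary.csv"))
    readr::write_csv(summary_df, csv)
    files <- c(files, csv)
  }
  if (save_png) {
    sw <- sweep_frame(evaluations, summary_df$strategy_or_subset)
    long <- rbind(
      data.frame(sweep = sw$sweep, strategy = sw$strategy,
                 accuracy = sw$test_balanced_accuracy, split = "test"),
      data.frame(sweep = sw$sweep, strategy = sw$strategy,
                 accuracy = sw$train_balanced_accuracy, split = "train"))
    p1 <- ggplot2::ggplot(long, ggplot2::aes(x = .data$sweep, y = .data$accuracy,
                                             colour = .data$strategy,
                                             linetype = .data$split)) +
      ggplot2::geom_line() +
      ggplot2::scale_linetype_manual(values = c(test = "solid", train = "dashed")) +
      ggplot2::labs(x = "sweep", y = "balanced accuracy") +
      ggplot2::ylim(0, 1) +
      ggplot2::theme_minimal()
    f1 <- file.path(output_folder, paste0(prefix, "_balanced_accuracy.png"))
    save_plot(p1, f1)
    p2 <- ggplot2::ggplot(summary_df,
                          ggplot2::aes(x = .data$mean_test_misclassified,
                                       y = .data$strategy_or_subset)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::geom_errorbarh(ggplot2::aes(
        xmin = pmax(0, .data$mean_test_misclassified - .data$std_test_misclassified),
        xmax = .data$mean_test_misclassified + .data$std_test_misclassified),
        height = 0.25) +
      ggplot2::labs(x = "mean misclassified test samples", y = NULL) +
      ggplot2::theme_minimal()
    f2 <- file.path(output_folder, paste0(prefix, "_misclassification.png"))
    save_plot(p2, f2)
    files <- c(files, f1, f2)
  }
  invisible(files)
}

#' Plot and export accuracy as a function of gene panel size
#'
#' @param size_map Named list mapping panel size to `panel_eval` (as
#'   returned by [run_multiple_gene_selections()]).
#' @param output_folder Writable output folder.
#' @param save_csv,save_png Output toggles.
#' @return Files written, invisibly.
#' @export
plot_multiple_gene_selections <- function(size_map, output_folder,
                                          save_csv = TRUE, save_png = TRUE) {
  if (length(size_map) == 0) stop("`size_map` must be non-empty", call. = FALSE)
  dir.create(output_folder, showWarnings = FALSE, recursive = TRUE)
  sizes <- as.integer(names(size_map))
  ord <- order(sizes)
  df <- summarize_evaluations(size_map[ord])
  df <- cbind(data.frame(panel_size = sizes[ord]),
              df[, setdiff(names(df), "strategy_or_subset")])
  files <- character(0)
  if (save_csv) {
    csv <- file.path(output_folder, "plot_multiple_gene_selections_summary.csv")
    readr::write_csv(df, csv)
    files <- c(files, csv)
  }
  if (save_png) {
    long <- rbind(
      data.frame(panel_size = df$panel_size, accuracy = df$mean_test_balanced_accuracy,
                 sd = df$std_test_balanced_accuracy, split = "test"),
      data.frame(panel_size = df$panel_size, accuracy = df$mean_train_balanced_accuracy,
                 sd = df$std_train_balanced_accuracy, split = "train"))
    p1 <- ggplot2::ggplot(long, ggplot2::aes(x = .data$panel_size, y = .data$accuracy,
                                             linetype = .data$split)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(0, .data$accuracy - .data$sd),
                                        ymax = pmin(1, .data$accuracy + .data$sd),
                                        group = .data$split), alpha = 0.15) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::scale_linetype_manual(values = c(test = "solid", train = "dashed")) +
      ggplot2::labs(x = "number of selected genes", y = "balanced accuracy") +
      ggplot2::theme_minimal()
    f1 <- file.path(output_folder, "plot_multiple_gene_selections_accuracy.png")
    save_plot(p1, f1)
    p2 <- ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$panel_size),
                                           y = .data$mean_test_misclassified)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::geom_errorbar(ggplot2::aes(
        ymin = pmax(0, .data$mean_test_misclassified - .data$std_test_misclassified),
        ymax = .data$mean_test_misclassified + .data$std_test_misclassified),
        width = 0.25) +
      ggplot2::labs(x = "number of selected genes",
                    y = "mean misclassified test samples") +
      ggplot2::theme_minimal()
    f2 <- file.path(output_folder, "plot_multiple_gene_selections_misclassification.png")
    save_plot(p2, f2)
    files <- c(files, f1, f2)
  }
  invisible(files)
}

#' Plot and export ranked gene subsets from an explorative search
#'
#' The chart shows the `top_n_display` best subsets (shorthand labels
#' S1, S2, ... in rank order, legend mapping labels to gene panels,
#' bars annotated mean +/- sd); the CSV contains every evaluated subset.
#' `delta_accuracy` optionally adds the difference in mean test accuracy
#' from the top-ranked subset.
#'
#' @param subset_map A `subset_map`.
#' @param top_n_display Number of subsets to display (clamped to the map
#'   size); must be positive.
#' @param output_folder Writable output folder.
#' @param save_csv,save_png Output toggles.
#' @param delta_accuracy Add a `delta_accuracy` column relative to the
#'   best subset.
#' @return Files written, invisibly.
#' @export
plot_explorative_gene_selections <- function(subset_map, top_n_display = 10L,
                                             output_folder, save_csv = TRUE,
                                             save_png = TRUE,
                                             delta_accuracy = FALSE) {
  if (length(subset_map) == 0) stop("`subset_map` must be non-empty", call. = FALSE)
  if (top_n_display <= 0) stop("`top_n_display` must be positive", call. = FALSE)
  dir.create(output_folder, showWarnings = FALSE, recursive = TRUE)
  df <- summarize_evaluations(subset_map)
  names(df)[names(df) == "strategy_or_subset"] <- "gene_subset"
  if (delta_accuracy) {
    df$delta_accuracy <- df$mean_test_balanced_accuracy -
      df$mean_test_balanced_accuracy[1]
  }
  files <- character(0)
  if (save_csv) {
    csv <- file.path(output_folder, "plot_explorative_gene_selections_ranked.csv")
    readr::write_csv(df, csv)
    files <- c(files, csv)
  }
  if (save_png) {
    k <- min(top_n_display, nrow(df))
    shown <- df[seq_len(k), , drop = FALSE]
    shown$label <- factor(paste0("S", seq_len(k)), levels = paste0("S", k:1))
    legend <- paste0("S", seq_len(k), " = ", shown$gene_subset, collapse = "\n")
    p <- ggplot2::ggplot(shown, ggplot2::aes(x = .data$mean_test_balanced_accuracy,
                                             y = .data$label)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::geom_errorbarh(ggplot2::aes(
        xmin = pmax(0, .data$mean_test_balanced_accuracy - .data$std_test_balanced_accuracy),
        xmax = pmin(1, .data$mean_test_balanced_accuracy + .data$std_test_balanced_accuracy)),
        height = 0.25) +
      ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f ± %.3f",
                                                      .data$mean_test_balanced_accuracy,
                                                      .data$std_test_balanced_accuracy)),
                         hjust = -0.05, size = 3) +
      ggplot2::labs(x = "mean test balanced accuracy", y = NULL, caption = legend) +
      ggplot2::xlim(0, 1.05) +
      ggplot2::theme_minimal() +
      ggplot2::theme(plot.caption = ggplot2::element_text(hjust = 0, size = 7))
    f <- file.path(output_folder, "plot_explorative_gene_selections_top_subsets.png")
    save_plot(p, f)
    files <- c(files, f)
  }
  invisible(files)
}

#' Export the per-sweep results of evaluations to CSV
#'
#' Schema: `sweep,mode_id,train_balanced_accuracy,test_balanced_accuracy,`
#' `test_misclassified,n_test` plus a `strategy` column when several
#' evaluations are given.
#'
#' @param evaluations List of `panel_eval` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(evaluations, path) {
  sw <- sweep_frame(evaluations)
  sw <- sw[, c("sweep", "mode_id", "train_balanced_accuracy",
               "test_balanced_accuracy", "test_misclassified", "n_test",
               "strategy")]
  readr::write_csv(sw, path)
  invisible(path)
}

#' @importFrom ggplot2 .data
NULL
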