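# Monte Carlo cross-validated panel evaluation: repeated stratified
# train/test splits, per-gene min-max normalization fitted on the
# training split, MLP fit, balanced accuracy + misclassification counts.

MODE_IDS <- c(SELECTED = 0L, RANDOM = 1L, ALL_GENES = 2L, CUSTOM = 3L)
RANDOM_GENE_SEED_OFFSET <- 10007L  # decouples gene sampling from splitting

#' Run configuration for panel classification
#'
#' @param number_sweeps Number of Monte Carlo cross-validation sweeps
#'   (default 10).
#' @param max_iterations Epoch cap for the MLP optimizer (default 500).
#' @param test_fraction Fraction of each class held out per sweep
#'   (default 0.2).
#' @param base_seed Base seed; sweep `i` uses `base_seed + i`.
#' @param hidden_layer_width Hidden layer width of the MLP (default 100).
#' @param mode Gene-pool semantics: one of `"SELECTED"`, `"CUSTOM"`,
#'   `"RANDOM"`, `"ALL_GENES"`.
#' @return A `run_config` list.
#' @export
run_config <- function(number_sweeps = 10L, max_iterations = 500L,
                       test_fraction = 0.2, base_seed = 0L,
                       hidden_layer_width = 100L, mode = "SELECTED") {
  mode <- match.arg(mode, names(MODE_IDS))
  number_sweeps <- as.integer(number_sweeps)
  max_iterations <- as.integer(max_iterations)
  if (number_sweeps < 1) stop("`number_sweeps` must be positive", call. = FALSE)
  if (max_iterations < 1) stop("`max_iterations` must be positive", call. = FALSE)
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("`test_fraction` must be strictly between 0 and 1", call. = FALSE)
  }
  structure(list(number_sweeps = number_sweeps,
                 max_iterations = max_iterations,
                 test_fraction = test_fraction,
                 base_seed = as.integer(base_seed),
                 hidden_layer_width = as.integer(hidden_layer_width),
                 mode = mode),
            class = "run_config")
}

#' Indices of genes with non-constant expression
#'
#' The candidate pool for all-genes classification and size-matched
#' random baselines: genes whose minimum and maximum across samples
#' differ.
#'
#' @param data A [labeled_matrix()].
#' @return Integer vector of column indices.
#' @export
non_constant_gene_indices <- function(data) {
  v <- data$values
  rng <- matrixStats_colRange(v)
  unname(which(rng[, 1] != rng[, 2]))
}

# colRange without a matrixStats dependency
matrixStats_colRange <- function(v) {
  cbind(apply(v, 2, min), apply(v, 2, max))
}

#' Min-max normalize train/test matrices on training statistics
#'
#' Each gene is affinely mapped so the training split spans \[0, 1\];
#' test values are clipped into \[0, 1\] so statistics never leak from
#' the evaluation side. Genes constant in the training split map to 0
#' everywhere.
#'
#' @param train_values,test_values Numeric matrices sharing gene columns.
#' @return List with normalized `train` and `test` matrices.
#' @export
minmax_normalize <- function(train_values, test_values) {
  lo <- apply(train_values, 2, min)
  hi <- apply(train_values, 2, max)
  span <- hi - lo
  const <- span == 0
  span[const] <- 1
  scale_mat <- function(m) {
    out <- sweep(sweep(m, 2, lo, "-"), 2, span, "/")
    out[out < 0] <- 0
    out[out > 1] <- 1
    out[, const] <- 0
    out
  }
  list(train = scale_mat(train_values), test = scale_mat(test_values))
}

#' Balanced accuracy for binary labels
#'
#' Mean of the per-class recalls, `(TP/(TP+FN) + TN/(TN+FP)) / 2`; 0.5 is
#' chance level regardless of class imbalance.
#'
#' @param true_labels,predicted_labels Equal-length 0/1 vectors; both
#'   classes must appear in `true_labels`.
#' @return Value in \[0, 1\].
#' @export
balanced_accuracy <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  if (length(unique(true_labels)) < 2) {
    stop("both classes must be present in `true_labels`", call. = FALSE)
  }
  rec <- vapply(c(0L, 1L), function(cls) {
    sel <- true_labels == cls
    mean(predicted_labels[sel] == cls)
  }, numeric(1))
  mean(rec)
}

# Stratified train/test index draw for one sweep. Redraws with an
# incremented sub-seed if a side loses a class (can only happen through
# degenerate class sizes), then errors after 10 attempts.
sweep_split <- function(labels, test_fraction, sweep_seed) {
  for (attempt in 0:9) {
    test_idx <- integer(0)
    for (cls in c(0L, 1L)) {
      idx <- which(labels == cls)
      n_test <- round(test_fraction * length(idx))
      n_test <- min(max(n_test, 1L), length(idx) - 1L)
      test_idx <- c(test_idx, withr::with_seed(sweep_seed + attempt * 1000003L + cls,
                                               sample(idx, n_test)))
    }
    train_idx <- setdiff(seq_along(labels), test_idx)
    if (length(unique(labels[train_idx])) == 2 && length(unique(labels[test_idx])) == 2) {
      return(list(train = sort(train_idx), test = sort(test_idx)))
    }
  }
  stop("could not draw a split containing both classes on each side", call. = FALSE)
}

#' One Monte Carlo sweep: split, normalize, fit, score
#'
#' @param data A [labeled_matrix()].
#' @param gene_indices Non-empty integer vector of gene columns to use.
#' @param sweep_seed Seed for this sweep's split and weight init.
#' @param cfg A [run_config()].
#' @param external_test Optional held-out [labeled_matrix()]; when given,
#'   the split is drawn within `data` for training only and evaluation
#'   uses `external_test`.
#' @param sweep_index Index recorded in the result (default 0).
#' @return A `sweep_result` one-row data frame: `sweep`, `mode_id`,
#'   `train_balanced_accuracy`, `test_balanced_accuracy`,
#'   `test_misclassified`, `n_test`.
#' @export
run_single_sweep <- function(data, gene_indices, sweep_seed, cfg = run_config(),
                             external_test = NULL, sweep_index = 0L) {
  if (length(gene_indices) == 0) stop("`gene_indices` must be non-empty", call. = FALSE)
  split <- sweep_split(data$labels, cfg$test_fraction, sweep_seed)
  Xtr <- data$values[split$train, gene_indices, drop = FALSE]
  ytr <- data$labels[split$train]
  if (is.null(external_test)) {
    Xte <- data$values[split$test, gene_indices, drop = FALSE]
    yte <- data$labels[split$test]
  } else {
    Xte <- external_test$values[, gene_indices, drop = FALSE]
    yte <- external_test$labels
  }
  norm <- minmax_normalize(Xtr, Xte)
  model <- mlp_fit(norm$train, ytr,
                   hidden = cfg$hidden_layer_width,
                   max_iter = cfg$max_iterations,
                   seed = sweep_seed)
  pred_tr <- mlp_predict(model, norm$train)
  pred_te <- mlp_predict(model, norm$test)
  data.frame(sweep = as.integer(sweep_index),
             mode_id = MODE_IDS[[cfg$mode]],
             train_balanced_accuracy = balanced_accuracy(ytr, pred_tr),
             test_balanced_accuracy = balanced_accuracy(yte, pred_te),
             test_misclassified = sum(pred_te != yte),
             n_test = length(yte))
}

new_panel_eval <- function(gene_names, mode, sweeps) {
  stopifnot(is.data.frame(sweeps))
  structure(list(gene_names = gene_names, mode = mode, sweeps = sweeps),
            class = "panel_eval")
}

#' Summary statistics of a panel evaluation
#'
#' @param object A `panel_eval`.
#' @param ... Unused.
#' @return Named list of means and sample (n-1) standard deviations of
#'   the per-sweep metrics (single-sweep evaluations report 0 sd).
#' @export
summary.panel_eval <- function(object, ...) {
  s <- object$sweeps
  sd0 <- function(v) if (length(v) < 2) 0 else sd(v)
  list(mean_train_balanced_accuracy = mean(s$train_balanced_accuracy),
       std_train_balanced_accuracy = sd0(s$train_balanced_accuracy),
       mean_test_balanced_accuracy = mean(s$test_balanced_accuracy),
       std_test_balanced_accuracy = sd0(s$test_balanced_accuracy),
       mean_test_misclassified = mean(s$test_misclassified),
       std_test_misclassified = sd0(s$test_misclassified),
       n_sweeps = nrow(s))
}

#' @export
print.panel_eval <- function(x, ...) {
  sm <- summary(x)
  cat("<panel_eval> mode ", x$mode, ", ", length(x$gene_names), " gene(s): ",
      paste(head(x$gene_names, 6), collapse = ", "),
      if (length(x$gene_names) > 6) ", ..." else "", "\n", sep = "")
  cat(sprintf("  test balanced accuracy %.3f +/- %.3f over %d sweeps\n",
              sm$mean_test_balanced_accuracy, sm$std_test_balanced_accuracy,
              sm$n_sweeps))
  invisible(x)
}

#' Core engine: repeated MLP classification of one gene panel
#'
#' Runs `number_sweeps` Monte Carlo sweeps with `sweep_seed = base_seed +
#' sweep_index`. In `RANDOM` mode a fresh equal-size gene sample is drawn
#' from the non-constant pool each sweep (seeded independently of the
#' split). With `external_test`, training splits are drawn inside `data`
#' and every sweep is evaluated on the held-out matrix, supporting the
#' split-before-ranking anti-circularity pipeline.
#'
#' @param data A [labeled_matrix()].
#' @param gene_indices Gene columns of the panel (for `RANDOM` mode this
#'   sets the panel size; the pool is all non-constant genes).
#' @param cfg A [run_config()]; its `mode` tags the results.
#' @param external_test Optional held-out [labeled_matrix()].
#' @return A `panel_eval`.
#' @export
run_gene_classification <- function(data, gene_indices, cfg = run_config(),
                                    external_test = NULL) {
  validate_labeled_matrix(data)
  if (length(gene_indices) == 0) stop("`gene_indices` must be non-empty", call. = FALSE)
  pool <- if (cfg$mode == "RANDOM") non_constant_gene_indices(data) else NULL
  sweeps <- lapply(seq_len(cfg$number_sweeps) - 1L, function(i) {
    sweep_seed <- cfg$base_seed + i
    idx <- gene_indices
    if (cfg$mode == "RANDOM") {
      k <- min(length(gene_indices), length(pool))
      idx <- withr::with_seed(sweep_seed + RANDOM_GENE_SEED_OFFSET, sample(pool, k))
    }
    run_single_sweep(data, idx, sweep_seed, cfg, external_test, sweep_index = i)
  })
  nm <- if (cfg$mode == "RANDOM") {
    paste0("random_", length(gene_indices), "_genes")
  } else gene_names(data)[gene_indices]
  res <- new_panel_eval(nm, cfg$mode, do.call(rbind, sweeps))
  if (isTRUE(getOption("panelscreen.verbose"))) log_peak_memory()
  res
}

#' Evaluate the top-n ranked genes, optionally with a random baseline
#'
#' @param data A [labeled_matrix()].
#' @param ranking An `mi_ranking` (from [rank_genes()] or
#'   [mock_ranking()]).
#' @param top_n Number of top-ranked genes to evaluate.
#' @param include_random Also evaluate equal-size random panels.
#' @param cfg A [run_config()].
#' @return List of `panel_eval` (length 1, or 2 with the random
#'   baseline).
#' @export
run_selected_genes <- function(data, ranking, top_n, include_random = FALSE,
                               cfg = run_config()) {
  if (top_n <= 0) stop("`top_n` must be positive", call. = FALSE)
  if (top_n > nrow(ranking)) {
    stop("`top_n` (", top_n, ") exceeds ranking size (", nrow(ranking), ")",
         call. = FALSE)
  }
  idx <- ranking$feature_index[seq_len(top_n)]
  out <- list(run_gene_classification(data, idx, modify_mode(cfg, "SELECTED")))
  if (include_random) {
    out <- c(out, list(run_gene_classification(data, idx, modify_mode(cfg, "RANDOM"))))
  }
  out
}

modify_mode <- function(cfg, mode) {
  cfg$mode <- match.arg(mode, names(MODE_IDS))
  cfg
}

#' Evaluate a user-defined gene panel, optionally with a random baseline
#'
#' @param data A [labeled_matrix()].
#' @param custom_genes Character vector of gene names (all-or-nothing
#'   resolution; duplicates dropped with a warning).
#' @param include_random Also evaluate equal-size random panels.
#' @param cfg A [run_config()].
#' @return List of `panel_eval`.
#' @export
run_with_custom_gene_set <- function(data, custom_genes, include_random = FALSE,
                                     cfg = run_config()) {
  ranking <- mock_ranking(custom_genes, data)
  idx <- ranking$feature_index
  out <- list(run_gene_classification(data, idx, modify_mode(cfg, "CUSTOM")))
  if (include_random) {
    out <- c(out, list(run_gene_classification(data, idx, modify_mode(cfg, "RANDOM"))))
  }
  out
}

#' Evaluate all non-constant genes as one panel
#'
#' The recommended first pass on a new dataset: if even the full
#' non-constant gene set classifies at chance level, the groups carry no
#' detectable expression signal and further analysis is unlikely to pay
#' off.
#'
#' @param data A [labeled_matrix()].
#' @param cfg A [run_config()].
#' @return A `panel_eval`.
#' @export
run_all_genes <- function(data, cfg = run_config()) {
  idx <- non_constant_gene_indices(data)
  if (length(idx) == 0) stop("no non-constant genes in the data", call. = FALSE)
  run_gene_classification(data, idx, modify_mode(cfg, "ALL_GENES"))
}

#' Benchmark classification across panel sizes
#'
#' Evaluates the top-`size` ranked genes for every requested size with a
#' shared base seed so the accuracy-vs-size curves are comparable.
#'
#' @param data A [labeled_matrix()].
#' @param ranking An `mi_ranking`.
#' @param sizes Vector of positive panel sizes, each at most the ranking
#'   size.
#' @param cfg A [run_config()].
#' @return Named list mapping size to `panel_eval` (empty list for empty
#'   `sizes`).
#' @export
run_multiple_gene_selections <- function(data, ranking, sizes, cfg = run_config()) {
  if (length(sizes) == 0) return(structure(list(), names = character(0)))
  sizes <- as.integer(sizes)
  bad <- sizes <= 0 | sizes > nrow(ranking)
  if (any(bad)) {
    stop("invalid panel size(s): ", paste(sizes[bad], collapse = ", "),
         " (ranking holds ", nrow(ranking), " genes)", call. = FALSE)
  }
  out <- lapply(sizes, function(k) {
    run_selected_genes(data, ranking, k, include_random = FALSE, cfg = cfg)[[1]]
  })
  names(out) <- as.character(sizes)
  out
}

#' Log peak memory used by the R session
#'
#' Reports the session's maximum memory footprint (as tracked by the
#' garbage collector) so long runs on large dense matrices can be
#' monitored against system capacity.
#'
#' @return The peak in MiB, invisibly.
#' @export
log_peak_memory <- function() {
  g <- gc(full = FALSE)
  peak_mb <- sum(g[, 6])   # "max used" in Mb for Ncells + Vcells
  message(sprintf("peak memory: %.1f MiB", peak_mb))
  invisible(peak_mb)
}
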