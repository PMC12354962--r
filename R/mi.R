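# Mutual-information gene ranking with Sturges-rule adaptive binning and
# a per-bin support guard against unstable estimates on skewed or
# zero-inflated genes.

#' Configuration for mutual-information ranking
#'
#' @param n_bins `"auto"` (Sturges' rule on the sample count) or an
#'   explicit integer >= 2.
#' @param min_datapoints_per_bin Minimum number of samples every bin
#'   (including empty ones) must hold for an MI estimate to be trusted at
#'   a given bin count; default 10.
#' @param log_base Logarithm base for the MI sum; base 2 gives scores in
#'   bits, bounded by 1 for a binary label.
#' @param top_k Optional cap on the number of returned genes (applied
#'   after sorting and exclusion).
#' @param exclusion_list Character vector of gene names removed from the
#'   ranked output post hoc (exact, case-sensitive match).
#' @return An `mi_config` list.
#' @export
mi_config <- function(n_bins = "auto", min_datapoints_per_bin = 10L,
                      log_base = 2, top_k = NULL, exclusion_list = character(0)) {
  if (!identical(n_bins, "auto")) {
    n_bins <- as.integer(n_bins)
    if (is.na(n_bins) || n_bins < 2) stop("explicit `n_bins` must be >= 2", call. = FALSE)
  }
  min_datapoints_per_bin <- as.integer(min_datapoints_per_bin)
  if (min_datapoints_per_bin < 1) stop("`min_datapoints_per_bin` must be >= 1", call. = FALSE)
  if (!is.numeric(log_base) || log_base <= 1) stop("`log_base` must be > 1", call. = FALSE)
  structure(list(n_bins = n_bins,
                 min_datapoints_per_bin = min_datapoints_per_bin,
                 log_base = log_base,
                 top_k = if (is.null(top_k)) NULL else as.integer(top_k),
                 exclusion_list = as.character(exclusion_list)),
            class = "mi_config")
}

#' Sturges-rule bin count
#'
#' `ceiling(1 + log2(n))`, floored at 2 bins. Kept intentionally low so
#' each bin retains enough support; resolution can be raised by setting
#' `n_bins` explicitly in [mi_config()].
#'
#' @param n_samples Number of samples (>= 2).
#' @return Integer bin count.
#' @export
compute_bin_count <- function(n_samples) {
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 2) stop("`n_samples` must be >= 2", call. = FALSE)
  max(2L, as.integer(ceiling(1 + log2(n_samples))))
}

#' Equal-width discretization of one gene's expression
#'
#' The expression range is cut into `n_bins` equal intervals; bin `b`
#' (0-based) covers `[min + b*w, min + (b+1)*w)` with the last bin closed
#' on the right so the maximum is included. A constant vector falls
#' entirely into bin 0.
#'
#' @param values Finite numeric vector.
#' @param n_bins Integer >= 2.
#' @return Integer vector of 0-based bin assignments.
#' @export
discretize_gene <- function(values, n_bins) {
  n_bins <- as.integer(n_bins)
  if (n_bins < 2) stop("`n_bins` must be >= 2", call. = FALSE)
  if (any(!is.finite(values))) stop("expression values must be finite", call. = FALSE)
  lo <- min(values); hi <- max(values)
  if (hi == lo) return(integer(length(values)))
  b <- as.integer(floor((values - lo) / (hi - lo) * n_bins))
  b[b >= n_bins] <- n_bins - 1L      # right-closure of the last bin
  b
}

#' Empirical mutual information between bin assignments and labels
#'
#' Plug-in estimate over the empirical joint histogram:
#' `I = sum p(b,c) * log(p(b,c) / (p(b) p(c)))` with `0 log 0 = 0`,
#' clamped at 0 against negative rounding error.
#'
#' @param bins Integer vector of bin assignments.
#' @param labels Vector of 0/1 labels, same length.
#' @param log_base Logarithm base (default 2: bits).
#' @return Non-negative MI estimate.
#' @export
mutual_information_score <- function(bins, labels, log_base = 2) {
  if (length(bins) != length(labels)) {
    stop("`bins` and `labels` must have equal length", call. = FALSE)
  }
  n <- length(bins)
  if (n < 1) stop("need at least one sample", call. = FALSE)
  joint <- table(bins, labels) / n
  px <- rowSums(joint)
  py <- colSums(joint)
  expected <- outer(px, py)
  nz <- joint > 0
  mi <- sum(joint[nz] * log(joint[nz] / expected[nz], base = log_base))
  max(0, mi)
}

# Adaptive support guard: starting at `start_bins`, require every bin
# (occupied or empty) to hold >= min_per_bin samples; on failure decrement
# the bin count and retry down to 2 bins. Returns the accepted assignment
# or supported = FALSE if even 2 bins fail.
guarded_bins <- function(values, start_bins, min_per_bin) {
  for (nb in seq(from = start_bins, to = 2L)) {
    b <- discretize_gene(values, nb)
    counts <- tabulate(b + 1L, nbins = nb)
    if (all(counts >= min_per_bin)) {
      return(list(bins = b, n_bins = nb, supported = TRUE))
    }
  }
  list(bins = NULL, n_bins = NA_integer_, supported = FALSE)
}

new_mi_ranking <- function(gene_name, feature_index, mi_score, supported) {
  structure(data.frame(gene_name = as.character(gene_name),
                       feature_index = as.integer(feature_index),
                       mi_score = as.numeric(mi_score),
                       supported = as.logical(supported),
                       stringsAsFactors = FALSE),
            class = c("mi_ranking", "data.frame"))
}

sort_mi_ranking <- function(tab) {
  tab <- tab[order(-tab$mi_score, tab$feature_index), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Rank genes by mutual information with the group label
#'
#' For each gene, expression is discretized at the configured (or
#' Sturges) bin count; if any bin holds fewer than
#' `min_datapoints_per_bin` samples the bin count is reduced stepwise to
#' 2, and a gene whose 2-bin histogram still lacks support is scored 0
#' with `supported = FALSE`. Genes are sorted by score (ties broken by
#' ascending column index), names on the exclusion list are dropped post
#' hoc, and the result is optionally truncated to `top_k`.
#'
#' When `cache_folder` is given, a previously cached ranking for the
#' same configuration is loaded instead of recomputing, and fresh
#' rankings are cached there as CSV.
#'
#' @param data A [labeled_matrix()].
#' @param cfg An [mi_config()].
#' @param cache_folder Optional folder for the ranking cache.
#' @return An `mi_ranking` data frame: `gene_name`, `feature_index`,
#'   `mi_score`, `supported`.
#' @export
rank_genes <- function(data, cfg = mi_config(), cache_folder = NULL) {
  validate_labeled_matrix(data)
  stopifnot(inherits(cfg, "mi_config"))
  if (!is.null(cache_folder)) {
    cached <- load_cached_ranking(cache_folder, cfg)
    if (!is.null(cached)) return(cached)
  }
  start_bins <- if (identical(cfg$n_bins, "auto")) {
    compute_bin_count(n_samples(data))
  } else cfg$n_bins
  ng <- n_genes(data)
  scores <- numeric(ng)
  supported <- logical(ng)
  for (j in seq_len(ng)) {
    g <- guarded_bins(data$values[, j], start_bins, cfg$min_datapoints_per_bin)
    if (g$supported) {
      scores[j] <- mutual_information_score(g$bins, data$labels, cfg$log_base)
      supported[j] <- TRUE
    }
  }
  tab <- sort_mi_ranking(new_mi_ranking(gene_names(data), seq_len(ng), scores, supported))
  if (length(cfg$exclusion_list)) {
    tab <- tab[!(tab$gene_name %in% cfg$exclusion_list), , drop = FALSE]
    rownames(tab) <- NULL
  }
  if (!is.null(cfg$top_k)) {
    tab <- head(tab, cfg$top_k)
  }
  class(tab) <- c("mi_ranking", "data.frame")
  if (!is.null(cache_folder)) cache_ranking(tab, cache_folder, cfg)
  tab
}

#' Mock ranking for a user-defined gene panel
#'
#' Bypasses MI computation entirely: every gene of the custom list gets
#' the placeholder score 1 so downstream classification and subset
#' search treat the panel exactly like a ranked one. Resolution is
#' all-or-nothing; records keep the user-given order.
#'
#' @param custom_genes Ordered character vector of gene names.
#' @param data A [labeled_matrix()] in which the names must resolve.
#' @return An `mi_ranking` with `mi_score = 1` and `supported = TRUE`
#'   for every listed gene, in user order.
#' @export
mock_ranking <- function(custom_genes, data) {
  custom_genes <- as.character(custom_genes)
  dup <- duplicated(custom_genes)
  if (any(dup)) {
    warning("duplicate gene names in custom list deduplicated: ",
            paste(unique(custom_genes[dup]), collapse = ", "), call. = FALSE)
    custom_genes <- custom_genes[!dup]
  }
  idx <- resolve_genes(data, custom_genes)
  new_mi_ranking(custom_genes, idx, rep(1, length(idx)), rep(TRUE, length(idx)))
}

ranking_cache_key <- function(cfg) {
  digest::digest(list(n_bins = cfg$n_bins,
                      min_datapoints_per_bin = cfg$min_datapoints_per_bin,
                      log_base = cfg$log_base,
                      top_k = cfg$top_k,
                      exclusion_list = sort(cfg$exclusion_list)),
                 algo = "xxhash32")
}

ranking_cache_path <- function(folder, cfg) {
  file.path(folder, paste0("mi_ranking_", ranking_cache_key(cfg), ".csv"))
}

#' Cache a ranking table as CSV
#'
#' Scores are written with 17 significant digits so the cache round trip
#' is value-exact. The filename is keyed by a hash of the configuration,
#' one file per (dataset folder, config).
#'
#' @param table An `mi_ranking`.
#' @param folder Cache folder (created if absent).
#' @param cfg The [mi_config()] that produced the table.
#' @return The cache file path, invisibly.
#' @export
cache_ranking <- function(table, folder, cfg = mi_config()) {
  dir.create(folder, showWarnings = FALSE, recursive = TRUE)
  path <- ranking_cache_path(folder, cfg)
  out <- data.frame(gene_name = table$gene_name,
                    index_feature = table$feature_index,
                    mutual_information = sprintf("%.17g", table$mi_score),
                    supported = table$supported)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a cached ranking table
#'
#' Returns `NULL` when no cache file exists for the configuration (a
#' "not found" signal distinct from corruption); a present but unreadable
#' or malformed cache raises an error instructing deletion rather than
#' silently recomputing. Rows are re-sorted on load so the sortedness
#' invariant holds even for hand-edited files.
#'
#' @param folder Cache folder.
#' @param cfg The [mi_config()] used as the cache key.
#' @return An `mi_ranking`, or `NULL` if not cached.
#' @export
load_cached_ranking <- function(folder, cfg = mi_config()) {
  path <- ranking_cache_path(folder, cfg)
  if (!file.exists(path)) return(NULL)
  tab <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) NULL)
  ok <- !is.null(tab) &&
    all(c("gene_name", "index_feature", "mutual_information", "supported") %in% names(tab)) &&
    nrow(tab) > 0 && !anyNA(suppressWarnings(as.numeric(tab$mutual_information)))
  if (!ok) {
    stop("corrupt ranking cache at ", path,
         "; delete the file to allow recomputation", call. = FALSE)
  }
  sort_mi_ranking(new_mi_ranking(tab$gene_name, tab$index_feature,
                                 as.numeric(tab$mutual_information),
                                 as.logical(tab$supported)))
}
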