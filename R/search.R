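# Gene-subset space search: exhaustive enumeration for small candidate
# pools, greedy forward selection (optionally with beam search and swap
# refinement) for larger ones. Every panel's evaluation is seeded by a
# stable hash of its sorted gene names combined with the run seed, so
# results are a pure function of (data, configs) regardless of thread
# count or visit order, and greedy/exhaustive evaluations of the same
# subset coincide exactly.

EXHAUSTIVE_HARD_CAP <- 19L   # 20+ candidates mean 2^20 - 1 > 1e6 subsets

#' Search configuration for subset exploration
#'
#' @param top_n_genes Size of the candidate pool (top of the ranking).
#' @param greedy_threshold Pool size above which exhaustive enumeration
#'   gives way to greedy forward selection (default 10).
#' @param max_panel_size Cap on the greedy panel (default: pool size).
#' @param allow_swaps Enable swap refinement after each greedy
#'   acceptance (default off).
#' @param beam_width Number of best partial panels kept per greedy depth
#'   (default 1 = plain greedy).
#' @param num_threads Worker count for parallel panel evaluation, or
#'   `"auto"` for all available cores. Results are independent of this
#'   value.
#' @param improvement_tolerance Minimum mean-test-accuracy gain required
#'   to extend a panel (default 0: strict improvement).
#' @return A `search_config` list.
#' @export
search_config <- function(top_n_genes = 5L, greedy_threshold = 10L,
                          max_panel_size = NULL, allow_swaps = FALSE,
                          beam_width = 1L, num_threads = 1L,
                          improvement_tolerance = 0) {
  beam_width <- as.integer(beam_width)
  greedy_threshold <- as.integer(greedy_threshold)
  if (beam_width < 1) stop("`beam_width` must be >= 1", call. = FALSE)
  if (greedy_threshold < 1) stop("`greedy_threshold` must be >= 1", call. = FALSE)
  if (improvement_tolerance < 0) stop("`improvement_tolerance` must be >= 0", call. = FALSE)
  structure(list(top_n_genes = as.integer(top_n_genes),
                 greedy_threshold = greedy_threshold,
                 max_panel_size = if (is.null(max_panel_size)) NULL else as.integer(max_panel_size),
                 allow_swaps = isTRUE(allow_swaps),
                 beam_width = beam_width,
                 num_threads = num_threads,
                 improvement_tolerance = improvement_tolerance),
            class = "search_config")
}

resolve_threads <- function(num_threads) {
  if (identical(num_threads, "auto")) {
    n <- parallel::detectCores()
    if (is.na(n)) n <- 1L
    return(max(1L, n))
  }
  max(1L, as.integer(num_threads))
}

#' Enumerate all non-empty subsets of a candidate gene list
#'
#' Deterministic order: by subset size, then lexicographically by
#' candidate position. The count is `2^n - 1`, so pools beyond the hard
#' cap of 20 candidates (over one million subsets) are rejected with a
#' pointer to greedy mode rather than silently truncated.
#'
#' @param candidates Ordered character vector of gene names.
#' @return List of character vectors, each a subset respecting candidate
#'   order.
#' @export
enumerate_subsets <- function(candidates) {
  n <- length(candidates)
  if (n < 1) stop("need at least one candidate gene", call. = FALSE)
  if (n > EXHAUSTIVE_HARD_CAP) {
    stop("exhaustive enumeration of ", n, " candidates means 2^", n,
         " - 1 = ", format(2^n - 1, big.mark = ","),
         " subsets (over the 1e6-scale hard cap of ", EXHAUSTIVE_HARD_CAP,
         "); use greedy mode (run_greedy_selection) instead", call. = FALSE)
  }
  out <- vector("list", 2^n - 1)
  pos <- 1L
  for (k in seq_len(n)) {
    combos <- combn(n, k)
    for (j in seq_len(ncol(combos))) {
      out[[pos]] <- candidates[combos[, j]]
      pos <- pos + 1L
    }
  }
  out
}

subset_key <- function(genes) paste(genes, collapse = "+")

#' Seed derived from a gene subset's identity
#'
#' Stable 32-bit hash of the sorted gene names, folded with the run's
#' base seed. Makes panel evaluations order- and scheduler-independent.
#'
#' @param genes Character vector of gene names.
#' @param base_seed Integer run seed.
#' @return Integer seed below 2^31.
#' @export
subset_seed <- function(genes, base_seed = 0L) {
  h <- digest::digest(paste(sort(genes), collapse = "|"), algo = "xxhash32",
                      serialize = FALSE)
  val <- strtoi(substr(h, 1, 7), base = 16L)   # <= 2^28 - 1, always parseable
  as.integer((val + as.integer(base_seed)) %% 2147483647L)
}

# Evaluate a list of panels (character vectors of gene names), reusing a
# shared cache environment so each distinct subset is evaluated once.
# Panels are canonicalized to candidate-pool order (when given) so the
# same subset reached along different paths shares one key.
evaluate_panels <- function(panels, data, run_cfg, n_threads, cache,
                            mode = "SELECTED", candidates = NULL) {
  if (!is.null(candidates)) {
    panels <- lapply(panels, function(g) g[order(match(g, candidates))])
  }
  keys <- vapply(panels, subset_key, character(1))
  todo <- !vapply(keys, function(k) !is.null(cache[[k]]), logical(1)) &
    !duplicated(keys)
  todo_panels <- panels[todo]
  if (length(todo_panels)) {
    eval_one <- function(genes) {
      cfg <- run_cfg
      cfg$mode <- mode
      cfg$base_seed <- subset_seed(genes, run_cfg$base_seed)
      run_gene_classification(data, resolve_genes(data, genes), cfg)
    }
    results <- if (n_threads > 1 && length(todo_panels) > 1 &&
                   .Platform$OS.type == "unix") {
      parallel::mclapply(todo_panels, eval_one, mc.cores = n_threads)
    } else {
      lapply(todo_panels, eval_one)
    }
    for (i in seq_along(todo_panels)) {
      r <- results[[i]]
      if (inherits(r, "try-error")) stop(attr(r, "condition"))
      cache[[subset_key(todo_panels[[i]])]] <- r
    }
  }
  stats::setNames(lapply(keys, function(k) cache[[k]]), keys)
}

panel_score <- function(ev) summary(ev)$mean_test_balanced_accuracy

as_subset_map <- function(cache) {
  keys <- ls(cache)
  out <- stats::setNames(lapply(keys, function(k) cache[[k]]), keys)
  structure(out, class = "subset_map")
}

#' @export
print.subset_map <- function(x, ...) {
  scores <- vapply(x, panel_score, numeric(1))
  ord <- order(-scores)
  cat("<subset_map> ", length(x), " evaluated panel(s); top:\n", sep = "")
  for (i in head(ord, 5)) {
    cat(sprintf("  %.3f  %s\n", scores[i], names(x)[i]))
  }
  invisible(x)
}

#' Exhaustive or greedy search over the top-ranked gene pool
#'
#' With a pool of at most `greedy_threshold` genes, every non-empty
#' subset is evaluated; larger pools delegate to
#' [run_greedy_selection()]. Each subset's evaluation is seeded from its
#' own gene names (see [subset_seed()]).
#'
#' @param data A [labeled_matrix()].
#' @param ranking An `mi_ranking`.
#' @param cfg A [search_config()].
#' @param run_cfg A [run_config()].
#' @return A `subset_map`: named list (keys = gene names joined by `+`)
#'   of `panel_eval` objects.
#' @export
run_explorative_gene_selections <- function(data, ranking, cfg = search_config(),
                                            run_cfg = run_config()) {
  if (cfg$top_n_genes > nrow(ranking)) {
    stop("`top_n_genes` (", cfg$top_n_genes, ") exceeds ranking size (",
         nrow(ranking), ")", call. = FALSE)
  }
  candidates <- ranking$gene_name[seq_len(cfg$top_n_genes)]
  if (cfg$top_n_genes > cfg$greedy_threshold) {
    return(run_greedy_selection(data, ranking, cfg, run_cfg))
  }
  subsets <- enumerate_subsets(candidates)
  cache <- new.env(parent = emptyenv())
  evaluate_panels(subsets, data, run_cfg, resolve_threads(cfg$num_threads),
                  cache, candidates = candidates)
  as_subset_map(cache)
}

#' Exhaustive subset evaluation of a user-defined gene list
#'
#' All non-empty subsets of the custom list are evaluated through the
#' mock-ranking path, regardless of the greedy threshold.
#'
#' @param data A [labeled_matrix()].
#' @param custom_genes Character vector of gene names (must all
#'   resolve).
#' @param cfg A [search_config()].
#' @param run_cfg A [run_config()].
#' @return A `subset_map`.
#' @export
run_explorative_with_custom_set <- function(data, custom_genes,
                                            cfg = search_config(),
                                            run_cfg = run_config()) {
  ranking <- mock_ranking(custom_genes, data)
  subsets <- enumerate_subsets(ranking$gene_name)
  cache <- new.env(parent = emptyenv())
  evaluate_panels(subsets, data, run_cfg, resolve_threads(cfg$num_threads),
                  cache, mode = "CUSTOM", candidates = ranking$gene_name)
  as_subset_map(cache)
}

# Deterministic ordering of equal-score panels: by the candidate-pool
# position of their genes (lower feature index first).
panel_order_key <- function(genes, candidates) {
  paste(sprintf("%04d", sort(match(genes, candidates))), collapse = "")
}

#' Greedy forward selection with optional beam search and swaps
#'
#' Starting from the empty panel, each step evaluates every one-gene
#' extension of the current panel(s) and keeps the best `beam_width`
#' extensions by mean test balanced accuracy (ties resolved toward
#' lower-ranked candidate positions). The search stops when the best
#' extension gains no more than `improvement_tolerance` over the current
#' best panel, or when `max_panel_size` is reached. With `allow_swaps`,
#' each accepted panel is refined by [swap_refinement()]. The returned
#' map contains every panel evaluated along the way.
#'
#' @inheritParams run_explorative_gene_selections
#' @return A `subset_map` of all evaluated panels.
#' @export
run_greedy_selection <- function(data, ranking, cfg = search_config(),
                                 run_cfg = run_config()) {
  if (cfg$top_n_genes > nrow(ranking)) {
    stop("`top_n_genes` exceeds ranking size", call. = FALSE)
  }
  candidates <- ranking$gene_name[seq_len(cfg$top_n_genes)]
  if (length(candidates) == 0) stop("empty candidate pool", call. = FALSE)
  max_size <- if (is.null(cfg$max_panel_size)) length(candidates) else
    min(cfg$max_panel_size, length(candidates))
  n_threads <- resolve_threads(cfg$num_threads)
  cache <- new.env(parent = emptyenv())

  beam <- list(list(genes = character(0), score = -Inf))
  best_score <- -Inf
  depth <- 0L
  while (depth < max_size) {
    # even a perfect panel (accuracy 1) could not clear the tolerance
    if (1 <= best_score + cfg$improvement_tolerance) break
    depth <- depth + 1L
    children <- list()
    for (b in beam) {
      remaining <- setdiff(candidates, b$genes)
      for (g in remaining) {
        child <- c(b$genes, g)
        children[[length(children) + 1L]] <- child[order(match(child, candidates))]
      }
    }
    ckeys <- vapply(children, function(x) subset_key(sort(x)), character(1))
    children <- children[!duplicated(ckeys)]
    if (length(children) == 0) break
    evs <- evaluate_panels(children, data, run_cfg, n_threads, cache,
                           candidates = candidates)
    scores <- vapply(evs, panel_score, numeric(1))
    ord <- order(-scores,
                 vapply(children, function(g) panel_order_key(g, candidates),
                        character(1)))
    top_score <- scores[ord[1]]
    if (top_score <= best_score + cfg$improvement_tolerance) break
    keep <- ord[seq_len(min(cfg$beam_width, length(ord)))]
    beam <- lapply(keep, function(i) list(genes = children[[i]],
                                          score = scores[i]))
    if (cfg$allow_swaps) {
      beam <- lapply(beam, function(b) {
        refined <- swap_refinement(b$genes, setdiff(candidates, b$genes),
                                   data, run_cfg, cfg, cache,
                                   n_threads = n_threads,
                                   candidates = candidates)
        list(genes = refined,
             score = panel_score(cache[[subset_key(refined)]]))
      })
    }
    best_score <- max(vapply(beam, `[[`, numeric(1), "score"))
  }
  as_subset_map(cache)
}

#' Swap refinement of a selected panel
#'
#' Repeatedly evaluates every single swap of one in-panel gene for one
#' outside candidate and applies the best strictly improving swap, until
#' no swap improves or the round cap (panel size) is hit. An optional
#' escape from early suboptimal greedy acceptances.
#'
#' @param panel Non-empty character vector of selected gene names.
#' @param outside Character vector of candidate genes outside the panel.
#' @param data A [labeled_matrix()].
#' @param run_cfg A [run_config()].
#' @param cfg A [search_config()] (tie-breaking and threads).
#' @param cache Internal evaluation cache environment (created if
#'   missing).
#' @param n_threads Worker count.
#' @param candidates Full candidate pool, used for deterministic
#'   tie-breaking (defaults to `c(panel, outside)`).
#' @return The refined panel (character vector).
#' @export
swap_refinement <- function(panel, outside, data, run_cfg = run_config(),
                            cfg = search_config(), cache = NULL,
                            n_threads = 1L, candidates = NULL) {
  if (length(panel) == 0) stop("`panel` must be non-empty", call. = FALSE)
  if (length(outside) == 0) return(panel)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  if (is.null(candidates)) candidates <- c(panel, outside)
  canon <- function(g) g[order(match(g, candidates))]
  current <- canon(panel)
  cur_ev <- evaluate_panels(list(current), data, run_cfg, n_threads, cache,
                            candidates = candidates)[[1]]
  cur_score <- panel_score(cur_ev)
  for (round in seq_along(panel)) {
    swaps <- list()
    for (i in seq_along(current)) {
      for (g in setdiff(outside, current)) {
        cand <- current
        cand[i] <- g
        swaps[[length(swaps) + 1L]] <- cand
      }
    }
    if (length(swaps) == 0) break
    skeys <- vapply(swaps, function(x) subset_key(sort(x)), character(1))
    swaps <- swaps[!duplicated(skeys)]
    evs <- evaluate_panels(swaps, data, run_cfg, n_threads, cache,
                           candidates = candidates)
    scores <- vapply(evs, panel_score, numeric(1))
    ord <- order(-scores,
                 vapply(swaps, function(g) panel_order_key(g, candidates),
                        character(1)))
    if (scores[ord[1]] <= cur_score) break
    outside <- union(setdiff(outside, swaps[[ord[1]]]),
                     setdiff(current, swaps[[ord[1]]]))
    current <- canon(swaps[[ord[1]]])
    cur_score <- scores[ord[1]]
  }
  current
}
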