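# Synthetic two-group expression generators. These emulate the signal
# structures the pipeline must handle -- a null pair of near-duplicate
# groups, and planted markers of controlled effect size on a skewed,
# optionally zero-inflated background -- so every stage is testable
# without downloading real accessions.

#' Specification for a synthetic fixture
#'
#' @param n_per_group Samples per group (default 200).
#' @param n_genes Total genes (default 500).
#' @param n_informative Number of planted marker genes (default 5).
#' @param effect_size Between-group mean shift of each marker, in units
#'   of its within-group standard deviation (default 2).
#' @param dropout_probability Independent zero-inflation rate in
#'   \[0, 1) (default 0.1, a mild rate typical of deeply sequenced
#'   full-length protocols).
#' @param noise_fraction Relative scale of the perturbation applied to
#'   the duplicated group of a null pair: per-gene noise SD =
#'   `noise_fraction` x per-gene base SD (default 0.01, i.e. 1%
#'   Gaussian noise).
#' @param seed Integer seed; generators are pure functions of this spec.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_per_group = 200L, n_genes = 500L, n_informative = 5L,
                         effect_size = 2, dropout_probability = 0.1,
                         noise_fraction = 0.01, seed = 1L) {
  n_per_group <- as.integer(n_per_group)
  n_genes <- as.integer(n_genes)
  n_informative <- as.integer(n_informative)
  if (n_informative > n_genes) stop("`n_informative` must be <= `n_genes`", call. = FALSE)
  if (effect_size < 0) stop("`effect_size` must be >= 0", call. = FALSE)
  if (dropout_probability < 0 || dropout_probability >= 1) {
    stop("`dropout_probability` must be in [0, 1)", call. = FALSE)
  }
  if (noise_fraction < 0) stop("`noise_fraction` must be >= 0", call. = FALSE)
  structure(list(n_per_group = n_per_group, n_genes = n_genes,
                 n_informative = n_informative, effect_size = effect_size,
                 dropout_probability = dropout_probability,
                 noise_fraction = noise_fraction, seed = as.integer(seed)),
            class = "fixture_spec")
}

# Skewed count-like base matrix: per-gene log-normal magnitudes with
# gene-specific log-means, optional independent dropout.
base_expression <- function(n_samples, n_genes, dropout_probability) {
  mu <- rnorm(n_genes, mean = 1, sd = 0.7)
  X <- matrix(exp(rnorm(n_samples * n_genes, mean = rep(mu, each = n_samples),
                        sd = 0.5)),
              nrow = n_samples, ncol = n_genes)
  if (dropout_probability > 0) {
    keep <- matrix(rbinom(n_samples * n_genes, 1, 1 - dropout_probability),
                   nrow = n_samples)
    X <- X * keep
  }
  X
}

#' Generate a null pair: duplicated groups with fractional noise
#'
#' Draws a base matrix, labels it group 0, and builds group 1 as the
#' same matrix perturbed by zero-mean Gaussian noise whose per-gene SD
#' is `noise_fraction` of the gene's base SD. With the default 1% noise
#' the two groups are near-identical, so no classifier should find a
#' reliable label signal -- the negative control for the whole pipeline.
#'
#' @param spec A [fixture_spec()].
#' @return A [labeled_matrix()] of `2 * n_per_group` samples.
#' @export
generate_null_pair <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed, {
    base <- base_expression(spec$n_per_group, spec$n_genes,
                            spec$dropout_probability)
    gene_sd <- apply(base, 2, sd)
    noise <- matrix(rnorm(length(base)), nrow = nrow(base)) *
      rep(spec$noise_fraction * gene_sd, each = nrow(base))
    perturbed <- base + noise
    X <- rbind(base, perturbed)
    colnames(X) <- paste0("gene_", seq_len(spec$n_genes))
    labeled_matrix(X, rep(c(0L, 1L), each = spec$n_per_group),
                   sample_ids = paste0("cell_", seq_len(2 * spec$n_per_group)))
  })
}

#' Generate a two-group dataset with planted marker genes
#'
#' Non-informative genes are drawn identically for both groups. Each of
#' the `n_informative` planted markers has its group-1 values shifted
#' upward by `effect_size` times the gene's within-group standard
#' deviation (before dropout), so `effect_size` is directly the
#' standardized mean difference. Dropout is applied independently to all
#' entries afterwards.
#'
#' @param spec A [fixture_spec()].
#' @return List with `data` (a [labeled_matrix()]) and `markers`
#'   (character vector of planted marker gene names).
#' @export
generate_marker_dataset <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (spec$n_informative < 1) stop("`n_informative` must be >= 1", call. = FALSE)
  withr::with_seed(spec$seed, {
    n <- 2L * spec$n_per_group
    mu <- rnorm(spec$n_genes, mean = 1, sd = 0.7)
    X <- matrix(exp(rnorm(n * spec$n_genes, mean = rep(mu, each = n), sd = 0.5)),
                nrow = n, ncol = spec$n_genes)
    labels <- rep(c(0L, 1L), each = spec$n_per_group)
    marker_idx <- sort(sample(spec$n_genes, spec$n_informative))
    for (j in marker_idx) {
      shift <- spec$effect_size * sd(X[, j])
      X[labels == 1L, j] <- X[labels == 1L, j] + shift
    }
    if (spec$dropout_probability > 0) {
      keep <- matrix(rbinom(length(X), 1, 1 - spec$dropout_probability),
                     nrow = nrow(X))
      X <- X * keep
    }
    colnames(X) <- paste0("gene_", seq_len(spec$n_genes))
    data <- labeled_matrix(X, labels,
                           sample_ids = paste0("cell_", seq_len(n)))
    list(data = data, markers = colnames(X)[marker_idx])
  })
}

#' Write a fixture in the supported on-disk formats
#'
#' @param data A [labeled_matrix()].
#' @param folder Output folder (created if absent).
#' @param formats Any of `"csv"` (labeled-CSV dialect, value-exact round
#'   trip) and `"h5ad"` (round trip to storage precision).
#' @param name Base filename (default `"fixture"`).
#' @return Named character vector of files written, invisibly.
#' @export
write_fixture <- function(data, folder, formats = c("csv", "h5ad"),
                          name = "fixture") {
  formats <- match.arg(formats, c("csv", "h5ad"), several.ok = TRUE)
  dir.create(folder, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  if ("csv" %in% formats) {
    f <- file.path(folder, paste0(name, ".csv"))
    write_csv_labeled(data, f)
    files <- c(files, csv = f)
  }
  if ("h5ad" %in% formats) {
    f <- file.path(folder, paste0(name, ".h5ad"))
    write_h5ad_labeled(data, f)
    files <- c(files, h5ad = f)
  }
  invisible(files)
}
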