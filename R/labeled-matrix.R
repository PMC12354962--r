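#' Labeled expression matrix
#'
#' The central exchange type of the package: a dense numeric matrix of
#' expression values with samples as rows and genes as columns, together
#' with a binary 0/1 group label per sample. Expression units are taken
#' as provided (counts, normalized values, ...); the package never
#' normalizes implicitly.
#'
#' @param values Numeric matrix, rows = samples, columns = genes. Column
#'   names are the gene identifiers and must be unique and non-empty.
#' @param labels Vector coercible to integer with exactly the values 0
#'   and 1, one entry per sample. Both classes must be present.
#' @param sample_ids Optional character vector of sample identifiers;
#'   defaults to existing rownames or `sample_1, sample_2, ...`.
#'
#' @return An object of class `labeled_matrix`: a list with elements
#'   `values` (matrix with sample rownames and gene colnames) and
#'   `labels` (integer vector of 0/1).
#' @export
labeled_matrix <- function(values, labels, sample_ids = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (samples x genes)", call. = FALSE)
  }
  labels <- as.integer(labels)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(nrow(values)))
  }
  rownames(values) <- as.character(sample_ids)
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("gene_", seq_len(ncol(values)))
  }
  obj <- structure(list(values = values, labels = labels),
                   class = "labeled_matrix")
  validate_labeled_matrix(obj)
  obj
}

#' Validate a labeled expression matrix
#'
#' Checks the structural invariants: matching dimensions, exactly the two
#' label values 0 and 1 both present, all expression values finite, and a
#' bijective gene-name to column mapping.
#'
#' @param x A `labeled_matrix`.
#' @return `x`, invisibly; stops with a descriptive error on violation.
#' @export
validate_labeled_matrix <- function(x) {
  stopifnot(inherits(x, "labeled_matrix"))
  v <- x$values
  if (nrow(v) != length(x$labels)) {
    stop("number of samples (", nrow(v), ") != number of labels (",
         length(x$labels), ")", call. = FALSE)
  }
  lv <- sort(unique(x$labels))
  if (!identical(lv, c(0L, 1L))) {
    stop("labels must contain exactly the two values 0 and 1; found {",
         paste(lv, collapse = ", "), "}", call. = FALSE)
  }
  if (anyNA(v) || any(!is.finite(v))) {
    stop("expression values contain NA/NaN/Inf; refusing to repair data silently",
         call. = FALSE)
  }
  gn <- colnames(v)
  if (is.null(gn) || any(!nzchar(gn))) {
    stop("all genes must have non-empty names", call. = FALSE)
  }
  if (anyDuplicated(gn)) {
    stop("duplicate gene names after loading: ",
         paste(unique(gn[duplicated(gn)]), collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.labeled_matrix <- function(x, ...) {
  cat("<labeled_matrix> ", n_samples(x), " samples x ", n_genes(x), " genes; ",
      "labels: ", sum(x$labels == 0L), " x 0, ", sum(x$labels == 1L), " x 1\n",
      sep = "")
  invisible(x)
}

#' @rdname labeled_matrix
#' @param x A `labeled_matrix`.
#' @export
n_samples <- function(x) nrow(x$values)

#' @rdname labeled_matrix
#' @export
n_genes <- function(x) ncol(x$values)

#' @rdname labeled_matrix
#' @export
gene_names <- function(x) colnames(x$values)

#' @rdname labeled_matrix
#' @export
sample_ids <- function(x) rownames(x$values)

#' Gene table: name -> column index mapping
#'
#' @param x A `labeled_matrix`.
#' @return A data frame with columns `gene_name` and `feature_index`
#'   (1-based column index into the expression matrix).
#' @export
gene_table <- function(x) {
  data.frame(gene_name = gene_names(x),
             feature_index = seq_len(n_genes(x)),
             stringsAsFactors = FALSE)
}

#' Resolve gene names to column indices
#'
#' All-or-nothing resolution: if any name is missing the call fails and
#' lists every unresolvable name, so partially matched panels can never
#' be evaluated by accident.
#'
#' @param x A `labeled_matrix`.
#' @param genes Character vector of gene names.
#' @return Integer vector of column indices, in the order of `genes`.
#' @export
resolve_genes <- function(x, genes) {
  if (length(genes) == 0) stop("empty gene list", call. = FALSE)
  idx <- match(genes, gene_names(x))
  if (anyNA(idx)) {
    stop("gene name(s) not found in data: ",
         paste(genes[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  idx
}

# Restrict a labeled matrix to a sample subset (logical or integer index).
subset_samples <- function(x, i) {
  structure(list(values = x$values[i, , drop = FALSE],
                 labels = x$labels[i]),
            class = "labeled_matrix")
}
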