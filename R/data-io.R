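#' @importFrom stats rnorm rbinom sd quantile
#' @importFrom utils head combn
NULL

# ---------------------------------------------------------------------------
# h5ad (AnnData-on-HDF5) access.
#
# Only the pieces of the AnnData layout that this package needs are read:
# the main matrix X (dense array or CSR/CSC sparse group) and the sample
# annotation frame /obs. HDF5 stores arrays row-major while R is
# column-major, so a Python (n_obs, n_var) array arrives here with
# reversed dims and is transposed back to samples x genes.
# ---------------------------------------------------------------------------

h5_children <- function(path, group) {
  ls <- rhdf5::h5ls(path, recursive = TRUE)
  ls$name[ls$group == group]
}

read_h5ad_obs <- function(path) {
  attrs <- rhdf5::h5readAttributes(path, "obs")
  index_col <- if (!is.null(attrs[["_index"]])) attrs[["_index"]] else "_index"
  cols <- setdiff(h5_children(path, "/obs"), "__categories")
  out <- list()
  for (cl in cols) {
    obj <- paste0("obs/", cl)
    cattrs <- tryCatch(rhdf5::h5readAttributes(path, obj), error = function(e) list())
    enc <- cattrs[["encoding-type"]]
    if (!is.null(enc) && identical(enc, "categorical")) {
      grp <- rhdf5::h5read(path, obj)
      codes <- as.integer(grp$codes)
      cats <- as.character(grp$categories)
      vals <- rep(NA_character_, length(codes))
      vals[codes >= 0] <- cats[codes[codes >= 0] + 1L]
      out[[cl]] <- vals
    } else {
      v <- rhdf5::h5read(path, obj)
      if (is.list(v) && !is.null(v$codes)) {   # categorical without attrs
        codes <- as.integer(v$codes)
        cats <- as.character(v$categories)
        vals <- rep(NA_character_, length(codes))
        vals[codes >= 0] <- cats[codes[codes >= 0] + 1L]
        out[[cl]] <- vals
      } else {
        out[[cl]] <- as.vector(v)
      }
    }
  }
  list(columns = out, index_col = index_col)
}

read_h5ad_X <- function(path) {
  ls <- rhdf5::h5ls(path, recursive = FALSE)
  xrow <- ls[ls$name == "X", , drop = FALSE]
  if (nrow(xrow) == 0) stop("malformed h5ad container: no /X entry", call. = FALSE)
  if (xrow$otype == "H5I_GROUP") {
    attrs <- rhdf5::h5readAttributes(path, "X")
    shape <- as.numeric(attrs[["shape"]])       # (n_obs, n_var), Python order
    enc <- attrs[["encoding-type"]]
    if (is.null(enc)) enc <- "csr_matrix"
    data <- as.numeric(rhdf5::h5read(path, "X/data"))
    indices <- as.integer(rhdf5::h5read(path, "X/indices"))
    indptr <- as.numeric(rhdf5::h5read(path, "X/indptr"))
    dense <- matrix(0, nrow = shape[1], ncol = shape[2])
    if (grepl("^csr", enc)) {
      for (i in seq_len(shape[1])) {
        rng <- seq.int(indptr[i] + 1, indptr[i + 1], length.out = max(0, indptr[i + 1] - indptr[i]))
        if (length(rng)) dense[i, indices[rng] + 1L] <- data[rng]
      }
    } else if (grepl("^csc", enc)) {
      for (j in seq_len(shape[2])) {
        rng <- seq.int(indptr[j] + 1, indptr[j + 1], length.out = max(0, indptr[j + 1] - indptr[j]))
        if (length(rng)) dense[indices[rng] + 1L, j] <- data[rng]
      }
    } else {
      stop("unsupported sparse X encoding: ", enc, call. = FALSE)
    }
    dense
  } else {
    m <- rhdf5::h5read(path, "X")
    t(m)   # HDF5 row-major (n_obs, n_var) arrives as n_var x n_obs in R
  }
}

read_h5ad_var_names <- function(path) {
  attrs <- tryCatch(rhdf5::h5readAttributes(path, "var"), error = function(e) list())
  index_col <- if (!is.null(attrs[["_index"]])) attrs[["_index"]] else "_index"
  nm <- tryCatch(as.character(rhdf5::h5read(path, paste0("var/", index_col))),
                 error = function(e) NULL)
  nm
}

#' Summarize an h5ad expression container
#'
#' Read-only diagnostic pass over an AnnData HDF5 file: dimensions, the
#' sample annotation columns with their unique values, and the fraction
#' of zero entries. Intended as a quick look before choosing the
#' annotation column and group values for loading.
#'
#' @param path Path to an `.h5ad` file.
#' @return A `dataset_summary` object: list with `n_samples`, `n_genes`,
#'   `annotation_columns` (named list of unique values per column), and
#'   `sparsity_fraction` (fraction of zero entries, in \[0, 1\]).
#' @export
explore_dataset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  X <- tryCatch(read_h5ad_X(path), error = function(e) {
    stop("malformed h5ad container (", conditionMessage(e), ")", call. = FALSE)
  })
  obs <- read_h5ad_obs(path)
  ann <- obs$columns
  ann[[obs$index_col]] <- NULL
  summary <- structure(list(
    n_samples = nrow(X),
    n_genes = ncol(X),
    annotation_columns = lapply(ann, function(v) sort(unique(v))),
    sparsity_fraction = mean(X == 0)
  ), class = "dataset_summary")
  summary
}

#' @export
print.dataset_summary <- function(x, ...) {
  cat("<dataset_summary> ", x$n_samples, " samples x ", x$n_genes, " genes\n", sep = "")
  cat(sprintf("sparsity: %.1f%% zero entries\n", 100 * x$sparsity_fraction))
  for (nm in names(x$annotation_columns)) {
    v <- x$annotation_columns[[nm]]
    shown <- paste(head(v, 8), collapse = ", ")
    if (length(v) > 8) shown <- paste0(shown, ", ... (", length(v), " values)")
    cat("  ", nm, ": ", shown, "\n", sep = "")
  }
  invisible(x)
}

# Resolve duplicate gene names by suffixing ".1", ".2", ... in file order.
dedupe_gene_names <- function(nm) {
  if (!anyDuplicated(nm)) return(nm)
  dup <- unique(nm[duplicated(nm)])
  warning("duplicate gene names resolved by suffixing: ",
          paste(head(dup, 5), collapse = ", "),
          if (length(dup) > 5) " ..." else "", call. = FALSE)
  make.unique(nm, sep = ".")
}

#' Load a labeled two-group expression matrix from an h5ad file
#'
#' Keeps only the samples whose annotation value is one of the two
#' `filter_values`, encodes the group label as 0/1, and returns a dense
#' samples x genes matrix. The label encoding follows the order of
#' `filter_values`: first value -> 0, second -> 1. Passing the values in
#' the other order flips the encoding, so e.g. `c("alpha", "beta")`
#' labels alpha cells 0 and beta cells 1.
#'
#' @param path Path to an `.h5ad` file.
#' @param filter_column Name of the sample annotation column holding the
#'   group assignment.
#' @param filter_values Character vector of exactly two annotation values
#'   (ordered: first -> label 0, second -> label 1). If given unnamed in
#'   non-lexicographic order, the user order wins.
#' @return A list with `genes` (data frame of `gene_name`,
#'   `feature_index`) and `data` (a [labeled_matrix()]).
#' @export
load_h5ad_labeled <- function(path, filter_column, filter_values) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obs <- read_h5ad_obs(path)
  ann <- obs$columns
  if (!filter_column %in% names(ann)) {
    stop("annotation column '", filter_column, "' not found; available: ",
         paste(setdiff(names(ann), obs$index_col), collapse = ", "), call. = FALSE)
  }
  col <- as.character(ann[[filter_column]])
  filter_values <- as.character(filter_values)
  if (length(filter_values) != 2 || anyDuplicated(filter_values)) {
    stop("`filter_values` must name exactly two distinct groups (binary comparison)",
         call. = FALSE)
  }
  missing_vals <- setdiff(filter_values, col)
  if (length(missing_vals)) {
    stop("value(s) ", paste(missing_vals, collapse = ", "),
         " not present in column '", filter_column, "'; available: ",
         paste(sort(unique(col)), collapse = ", "), call. = FALSE)
  }
  keep <- which(col %in% filter_values)
  labels <- ifelse(col[keep] == filter_values[2], 1L, 0L)
  if (sum(labels == 0L) < 2 || sum(labels == 1L) < 2) {
    stop("each group needs at least 2 samples after filtering", call. = FALSE)
  }
  X <- read_h5ad_X(path)
  gn <- read_h5ad_var_names(path)
  if (is.null(gn)) gn <- paste0("gene_", seq_len(ncol(X)))
  gn <- dedupe_gene_names(gn)
  sample_names <- ann[[obs$index_col]]
  if (is.null(sample_names)) sample_names <- paste0("sample_", seq_len(nrow(X)))
  X <- X[keep, , drop = FALSE]
  colnames(X) <- gn
  data <- labeled_matrix(X, labels, sample_ids = sample_names[keep])
  list(genes = gene_table(data), data = data)
}

# ---------------------------------------------------------------------------
# Labeled-CSV dialect: header "gene_id,<sample ids>"; second row
# "label,<0/1 per sample>"; remaining rows one gene each (genes as rows,
# the common transcriptomics on-disk convention). In memory everything is
# samples x genes.
# ---------------------------------------------------------------------------

#' Load a labeled expression matrix from the labeled-CSV dialect
#'
#' @param path Path to a CSV file: header `gene_id,<sample ids>`, a
#'   `label` row of 0/1 per sample, then one row per gene.
#' @return A list with `genes` (gene table) and `data` (a
#'   [labeled_matrix()]), oriented samples x genes.
#' @export
load_csv_labeled <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, header = FALSE, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  if (nrow(raw) < 3) stop("labeled-CSV format error: need header, label row and >= 1 gene row",
                          call. = FALSE)
  header <- as.character(raw[1, ])
  if (header[1] != "gene_id") {
    stop("labeled-CSV format error: first header cell must be 'gene_id', found '",
         header[1], "'", call. = FALSE)
  }
  sample_names <- header[-1]
  label_row <- as.character(raw[2, ])
  if (label_row[1] != "label") {
    stop("labeled-CSV format error: second row must start with 'label' (missing label row?)",
         call. = FALSE)
  }
  labels <- suppressWarnings(as.numeric(label_row[-1]))
  if (anyNA(labels) || !all(labels %in% c(0, 1))) {
    stop("label values outside {0, 1} in label row", call. = FALSE)
  }
  body <- raw[-(1:2), , drop = FALSE]
  gene_ids <- dedupe_gene_names(as.character(body[, 1]))
  vals <- as.matrix(body[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop("non-numeric expression cell at gene row ", bad[1], " ('",
         gene_ids[bad[1]], "'), sample column ", bad[2], " ('",
         sample_names[bad[2]], "'): '", vals[bad[1], bad[2]], "'", call. = FALSE)
  }
  X <- t(num)                       # genes-as-rows on disk -> samples x genes
  colnames(X) <- gene_ids
  data <- labeled_matrix(X, as.integer(labels), sample_ids = sample_names)
  list(genes = gene_table(data), data = data)
}

#' Write a labeled expression matrix in the labeled-CSV dialect
#'
#' Values are emitted with `%.17g` so the CSV/loader round trip is
#' value-exact for doubles.
#'
#' @param data A [labeled_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_csv_labeled <- function(data, path) {
  validate_labeled_matrix(data)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("gene_id", sample_ids(data)), collapse = ","), con)
  writeLines(paste(c("label", data$labels), collapse = ","), con)
  fmt <- function(v) sprintf("%.17g", v)
  gm <- t(data$values)              # genes as rows on disk
  lines <- vapply(seq_len(nrow(gm)), function(i) {
    paste(c(rownames(gm)[i], fmt(gm[i, ])), collapse = ",")
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}

#' Write a labeled matrix as a minimal h5ad container
#'
#' Emits a dense AnnData-on-HDF5 layout (X, obs with a `group` column
#' and the 0/1 `label`, var with gene names) readable by standard
#' AnnData tooling and by [load_h5ad_labeled()].
#'
#' @param data A [labeled_matrix()].
#' @param path Output `.h5ad` path (overwritten if present).
#' @param group_names Character vector of length 2 naming groups 0 and 1
#'   in the `group` annotation column.
#' @return `path`, invisibly.
#' @export
write_h5ad_labeled <- function(data, path, group_names = c("group0", "group1")) {
  validate_labeled_matrix(data)
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  h5set <- function(obj, attrs) {
    fid <- rhdf5::H5Fopen(path)
    oid <- rhdf5::H5Oopen(fid, obj)
    for (nm in names(attrs)) rhdf5::h5writeAttribute(attrs[[nm]], oid, nm,
                                                     variableLengthString = TRUE,
                                                     asScalar = TRUE)
    rhdf5::H5Oclose(oid)
    rhdf5::H5Fclose(fid)
  }
  # t(): write n_var x n_obs from R so Python readers see (n_obs, n_var)
  rhdf5::h5write(t(data$values), path, "X")
  rhdf5::h5createGroup(path, "obs")
  rhdf5::h5write(sample_ids(data), path, "obs/_index")
  rhdf5::h5write(group_names[data$labels + 1L], path, "obs/group")
  rhdf5::h5write(as.integer(data$labels), path, "obs/label")
  rhdf5::h5createGroup(path, "var")
  rhdf5::h5write(gene_names(data), path, "var/_index")
  rhdf5::h5write(gene_names(data), path, "var/feature_name")
  h5set("/", list("encoding-type" = "anndata", "encoding-version" = "0.1.0"))
  h5set("X", list("encoding-type" = "array", "encoding-version" = "0.2.0"))
  df_attrs <- function(index, order) list("encoding-type" = "dataframe",
                                          "encoding-version" = "0.2.0",
                                          "_index" = index)
  fid <- rhdf5::H5Fopen(path)
  for (grp in c("obs", "var")) {
    oid <- rhdf5::H5Oopen(fid, grp)
    rhdf5::h5writeAttribute("dataframe", oid, "encoding-type",
                            variableLengthString = TRUE, asScalar = TRUE)
    rhdf5::h5writeAttribute("0.2.0", oid, "encoding-version",
                            variableLengthString = TRUE, asScalar = TRUE)
    rhdf5::h5writeAttribute("_index", oid, "_index",
                            variableLengthString = TRUE, asScalar = TRUE)
    cols <- if (grp == "obs") c("group", "label") else "feature_name"
    rhdf5::h5writeAttribute(cols, oid, "column-order", variableLengthString = FALSE)
    rhdf5::H5Oclose(oid)
  }
  rhdf5::H5Fclose(fid)
  for (ds in c("obs/_index", "obs/group", "var/_index", "var/feature_name")) {
    h5set(ds, list("encoding-type" = "string-array", "encoding-version" = "0.2.0"))
  }
  h5set("obs/label", list("encoding-type" = "array", "encoding-version" = "0.2.0"))
  rhdf5::h5closeAll()
  invisible(path)
}

# ---------------------------------------------------------------------------
# Stratified train/test split
# ---------------------------------------------------------------------------

#' Split a labeled matrix into stratified train and test parts
#'
#' Per class, `round(train_fraction * class size)` samples go to the
#' training part; the rest form the test part. Deterministic for a fixed
#' seed. Splitting before feature selection guards against circularity
#' when feature selection and final evaluation must not share data.
#'
#' @param data A [labeled_matrix()].
#' @param train_fraction Fraction of each class assigned to training,
#'   strictly between 0 and 1.
#' @param seed Integer seed for the sample shuffle.
#' @return A `split_dataset`: list with `train`, `test` (both
#'   `labeled_matrix`), `train_fraction`, `seed`.
#' @export
split_dataset <- function(data, train_fraction = 0.8, seed = 0L) {
  validate_labeled_matrix(data)
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must be strictly between 0 and 1", call. = FALSE)
  }
  train_idx <- integer(0)
  for (cls in c(0L, 1L)) {
    idx <- which(data$labels == cls)
    n_train <- round(train_fraction * length(idx))
    if (n_train < 1 || n_train >= length(idx)) {
      stop("class ", cls, " would receive ", n_train, " train and ",
           length(idx) - n_train, " test samples; adjust train_fraction",
           call. = FALSE)
    }
    picked <- withr::with_seed(seed + cls, sample(idx, n_train))
    train_idx <- c(train_idx, picked)
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(n_samples(data)), train_idx)
  structure(list(train = subset_samples(data, train_idx),
                 test = subset_samples(data, test_idx),
                 train_fraction = train_fraction,
                 seed = as.integer(seed)),
            class = "split_dataset")
}

#' @export
print.split_dataset <- function(x, ...) {
  cat("<split_dataset> train ", n_samples(x$train), " / test ",
      n_samples(x$test), " samples (fraction ", x$train_fraction,
      ", seed ", x$seed, ")\n", sep = "")
  invisible(x)
}
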