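# Loading, label encoding, the labeled-CSV dialect, h5ad round trips,
# and the stratified split.

test_that("labeled_matrix enforces its invariants", {
  v <- matrix(1:6, 3, 2, dimnames = list(NULL, c("a", "b")))
  expect_s3_class(labeled_matrix(v, c(0, 1, 1)), "labeled_matrix")
  expect_error(labeled_matrix(v, c(0, 0, 0)), "exactly the two values")
  expect_error(labeled_matrix(v, c(0, 1)), "number of labels")
  v2 <- v; v2[1, 1] <- NA
  expect_error(labeled_matrix(v2, c(0, 1, 1)), "NA/NaN/Inf")
  v3 <- v; colnames(v3) <- c("a", "a")
  expect_error(labeled_matrix(v3, c(0, 1, 1)), "duplicate gene names")
})

test_that("labeled-CSV round trip is value-identical", {
  d <- separable_fixture(n_per_group = 10, n_noise = 4)
  f <- tempfile(fileext = ".csv")
  write_csv_labeled(d, f)
  back <- load_csv_labeled(f)
  expect_identical(back$data$values, d$values)
  expect_identical(back$data$labels, d$labels)
  expect_identical(gene_names(back$data), gene_names(d))
  expect_identical(back$genes$gene_name, gene_names(d))
})

test_that("hand-written labeled CSV is transcribed exactly", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("gene_id,c1,c2,c3",
               "label,0,0,1",
               "INS,1.5,2,0",
               "GCG,0,3.25,4"), f)
  res <- load_csv_labeled(f)
  expect_equal(dim(res$data$values), c(3, 2))
  expect_equal(res$data$values[, "INS"], c(c1 = 1.5, c2 = 2, c3 = 0))
  expect_equal(res$data$values[, "GCG"], c(c1 = 0, c2 = 3.25, c3 = 4))
  expect_equal(res$data$labels, c(0L, 0L, 1L))
})

test_that("malformed labeled CSVs fail with located errors", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("gene_id,c1,c2,c3,c4", "label,0,0,1,2",
               "g1,1,2,3,4"), f)
  expect_error(load_csv_labeled(f), "outside \\{0, 1\\}")
  writeLines(c("gene_id,c1,c2", "g1,1,2"), f)
  expect_error(load_csv_labeled(f), "label row")
  writeLines(c("gene_id,c1,c2", "label,0,1", "g1,1,oops"), f)
  expect_error(load_csv_labeled(f), "non-numeric expression cell.*g1.*c2")
})

test_that("h5ad writer/reader round trip preserves values and annotations", {
  d <- separable_fixture(n_per_group = 5, n_noise = 3)
  f <- tempfile(fileext = ".h5ad")
  write_h5ad_labeled(d, f, group_names = c("alpha", "beta"))
  s <- explore_dataset(f)
  expect_equal(s$n_samples, 10)
  expect_equal(s$n_genes, 4)
  expect_setequal(s$annotation_columns$group, c("alpha", "beta"))
  res <- load_h5ad_labeled(f, "group", c("alpha", "beta"))
  expect_equal(res$data$values, d$values, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_identical(res$data$labels, d$labels)
  # explicit reversed order flips the encoding
  res2 <- load_h5ad_labeled(f, "group", c("beta", "alpha"))
  expect_identical(res2$data$labels, 1L - d$labels)
})

test_that("h5ad written here is readable by the Python AnnData stack and back", {
  d <- separable_fixture(n_per_group = 4, n_noise = 2)
  f <- tempfile(fileext = ".h5ad")
  f2 <- tempfile(fileext = ".h5ad")
  write_h5ad_labeled(d, f, group_names = c("ctrl", "treated"))
  script <- sprintf(
    "import anndata, scipy.sparse as sp; a = anndata.read_h5ad('%s'); \nassert a.shape == (8, 3), a.shape\nassert list(a.obs['group'])[:4] == ['ctrl']*4\na.X = sp.csr_matrix(a.X)\na.write_h5ad('%s')", f, f2)
  status <- suppressWarnings(system2("python", c("-c", shQuote(script)),
                                     stdout = TRUE, stderr = TRUE))
  expect_true(is.null(attr(status, "status")) || attr(status, "status") == 0,
              info = paste(status, collapse = "\n"))
  # sparse CSR h5ad written by anndata loads to the same matrix
  res <- load_h5ad_labeled(f2, "group", c("ctrl", "treated"))
  expect_equal(res$data$values, d$values, tolerance = 1e-6, ignore_attr = TRUE)
  expect_identical(res$data$labels, d$labels)
})

test_that("h5ad loader validates columns and values", {
  d <- separable_fixture(n_per_group = 5, n_noise = 2)
  f <- tempfile(fileext = ".h5ad")
  write_h5ad_labeled(d, f, group_names = c("a", "b"))
  expect_error(load_h5ad_labeled(f, "nope", c("a", "b")), "available: .*group")
  expect_error(load_h5ad_labeled(f, "group", c("a", "zzz")), "zzz")
  expect_error(load_h5ad_labeled(f, "group", c("a", "b", "c")), "exactly two")
  expect_error(explore_dataset(tempfile()), "not found")
})

test_that("stratified split honors per-class rounding and determinism", {
  withr::with_seed(2, {
    X <- matrix(rnorm(100 * 3), 100, dimnames = list(NULL, c("a", "b", "c")))
    d <- labeled_matrix(X, rep(c(0L, 1L), each = 50))
  })
  sp <- split_dataset(d, 0.8, seed = 9)
  expect_equal(n_samples(sp$train), 80)
  expect_equal(sum(sp$train$labels == 0), 40)
  expect_equal(sum(sp$test$labels == 1), 10)
  expect_length(intersect(sample_ids(sp$train), sample_ids(sp$test)), 0)
  expect_setequal(c(sample_ids(sp$train), sample_ids(sp$test)), sample_ids(d))
  sp2 <- split_dataset(d, 0.8, seed = 9)
  expect_identical(sample_ids(sp$train), sample_ids(sp2$train))
  sp3 <- split_dataset(d, 0.8, seed = 10)
  expect_false(identical(sample_ids(sp$train), sample_ids(sp3$train)))
  expect_error(split_dataset(d, 1.0), "strictly between")
  expect_error(split_dataset(d, 0.999), "train and")
})

test_that("loading permutes rows and labels together", {
  d <- separable_fixture(n_per_group = 6, n_noise = 2)
  f <- tempfile(fileext = ".csv")
  perm <- withr::with_seed(4, sample(n_samples(d)))
  dperm <- labeled_matrix(d$values[perm, ], d$labels[perm])
  write_csv_labeled(dperm, f)
  back <- load_csv_labeled(f)$data
  expect_identical(back$values, dperm$values)
  expect_identical(back$labels, d$labels[perm])
})

test_that("duplicate gene names are suffixed in file order with a warning", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("gene_id,c1,c2,c3,c4", "label,0,0,1,1",
               "G,1,2,3,4", "G,5,6,7,8", "H,0,0,0,1"), f)
  expect_warning(res <- load_csv_labeled(f), "duplicate gene names")
  expect_identical(gene_names(res$data), c("G", "G.1", "H"))
})
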