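# Mutual-information ranking: bin counts, discretization, the MI
# estimator against a brute-force oracle, the support guard, exclusion
# and mock scoring, and the cache round trip.

test_that("Sturges bin count is ceil(1 + log2(n)) with floor 2", {
  expect_equal(compute_bin_count(2), 2)
  expect_equal(compute_bin_count(256), 9)
  expect_equal(compute_bin_count(1000), 11)
  expect_error(compute_bin_count(1), ">= 2")
})

test_that("equal-width discretization covers the range with right-closed last bin", {
  expect_equal(discretize_gene(c(0, 1, 2, 3), 2), c(0L, 0L, 1L, 1L))
  expect_equal(discretize_gene(rep(4.2, 7), 3), rep(0L, 7))
  v <- c(0, 2.5, 5, 7.5, 10)
  b <- discretize_gene(v, 4)
  expect_equal(b, c(0L, 1L, 2L, 3L, 3L))   # max lands in the last bin
  expect_error(discretize_gene(c(1, NA), 2), "finite")
})

test_that("MI matches the brute-force double-sum oracle on random tables", {
  withr::with_seed(101, {
    for (rep in 1:300) {
      nb <- sample(2:12, 1)
      n <- sample(10:60, 1)
      bins <- sample(0:(nb - 1), n, replace = TRUE)
      labels <- sample(0:1, n, replace = TRUE)
      if (length(unique(labels)) < 2) labels[1:2] <- c(0L, 1L)
      base <- sample(c(2, exp(1), 10), 1)
      expect_equal(mutual_information_score(bins, labels, base),
                   max(0, mi_oracle(bins, labels, base)), tolerance = 1e-12)
    }
  })
})

test_that("MI attains known values at the extremes", {
  # bins identical to balanced labels: exactly 1 bit
  expect_equal(mutual_information_score(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1.0)
  # product joint table: exact independence
  bins <- rep(c(0, 1), times = 4)
  labels <- rep(c(0, 0, 1, 1), times = 2)
  expect_equal(mutual_information_score(bins, labels), 0)
  # constant bins carry no information
  expect_equal(mutual_information_score(rep(0, 8), rep(c(0, 1), 4)), 0)
  expect_error(mutual_information_score(1:3, 1:4), "equal length")
})

test_that("MI is bounded by 1 bit for binary labels and invariant to monotone maps", {
  withr::with_seed(77, {
    for (rep in 1:20) {
      x <- rlnorm(80)
      labels <- rep(c(0L, 1L), 40)
      nb <- compute_bin_count(80)
      b <- discretize_gene(x, nb)
      mi <- mutual_information_score(b, labels)
      expect_gte(mi, 0)
      expect_lte(mi, 1)
      # affine maps preserve equal-width assignments exactly
      expect_identical(discretize_gene(3 * x + 2, nb), b)
      # joint permutation of samples and labels leaves MI unchanged
      perm <- sample(80)
      expect_equal(mutual_information_score(b[perm], labels[perm]), mi)
    }
  })
})

test_that("rank_genes puts a perfectly separating gene first", {
  d <- separable_fixture(n_per_group = 100, n_noise = 49)
  tab <- rank_genes(d)
  expect_s3_class(tab, "mi_ranking")
  expect_equal(tab$gene_name[1], "marker")
  expect_equal(tab$mi_score[1], 1.0, tolerance = 1e-9)
  expect_true(all(diff(tab$mi_score) <= 0))
  # oracle recomputation of the top score
  nb_ok <- panelscreen:::guarded_bins(d$values[, "marker"],
                                      compute_bin_count(200), 10)
  expect_true(nb_ok$supported)
  expect_equal(tab$mi_score[1], mi_oracle(nb_ok$bins, d$labels))
})

test_that("exclusion list removes genes post hoc without reordering the rest", {
  d <- separable_fixture(n_per_group = 100, n_noise = 10)
  full <- rank_genes(d)
  excl <- rank_genes(d, mi_config(exclusion_list = "marker"))
  expect_false("marker" %in% excl$gene_name)
  expect_identical(excl$gene_name, setdiff(full$gene_name, "marker"))
  # top_k truncation happens after exclusion
  topk <- rank_genes(d, mi_config(exclusion_list = "marker", top_k = 3))
  expect_identical(topk$gene_name, excl$gene_name[1:3])
})

test_that("all-constant genes score 0 and tie-break by feature index", {
  X <- matrix(rep(c(1, 2, 7), each = 8), nrow = 8,
              dimnames = list(NULL, c("c1", "c2", "c3")))
  d <- labeled_matrix(X, rep(c(0L, 1L), 4))
  tab <- rank_genes(d)
  expect_equal(tab$mi_score, rep(0, 3))
  expect_false(any(tab$supported))
  expect_equal(tab$feature_index, 1:3)
})

test_that("the support guard decrements bins and flags hopeless genes", {
  # 90% zeros: Sturges bins fail, 2 bins hold (36 zeros / 4 non-zeros < 10 -> even
  # 2 bins fail); with min 2 per bin the 2-bin fallback succeeds
  x <- c(rep(0, 36), rep(10, 4))
  g10 <- panelscreen:::guarded_bins(x, compute_bin_count(40), 10)
  expect_false(g10$supported)
  g2 <- panelscreen:::guarded_bins(x, compute_bin_count(40), 2)
  expect_true(g2$supported)
  expect_equal(g2$n_bins, 2)
})

test_that("mock ranking assigns score 1 in user order, all-or-nothing", {
  d <- tiny_matrix()
  tab <- mock_ranking(c("gC", "gA"), d)
  expect_equal(tab$gene_name, c("gC", "gA"))
  expect_equal(tab$mi_score, c(1, 1))
  expect_true(all(tab$supported))
  expect_equal(tab$feature_index, c(3L, 1L))
  expect_error(mock_ranking(character(0), d), "empty")
  expect_error(mock_ranking(c("gA", "nope", "alsono"), d), "nope, alsono")
  expect_warning(tab2 <- mock_ranking(c("gA", "gA"), d), "duplicate")
  expect_equal(nrow(tab2), 1)
})

test_that("ranking cache round-trips exactly and detects corruption", {
  d <- separable_fixture(n_per_group = 50, n_noise = 8)
  folder <- tempfile()
  cfg <- mi_config()
  tab <- rank_genes(d, cfg, cache_folder = folder)
  cached <- load_cached_ranking(folder, cfg)
  expect_equal(cached$mi_score, tab$mi_score)
  expect_identical(cached$gene_name, tab$gene_name)
  # cache is preferred over recomputation: poison it and observe
  path <- panelscreen:::ranking_cache_path(folder, cfg)
  poisoned <- utils::read.csv(path)
  poisoned$mutual_information <- rev(poisoned$mutual_information)
  utils::write.csv(poisoned, path, row.names = FALSE, quote = FALSE)
  tab2 <- rank_genes(d, cfg, cache_folder = folder)
  expect_false(identical(tab2$gene_name, tab$gene_name))
  # shuffled rows are re-sorted on load
  expect_true(all(diff(tab2$mi_score) <= 0))
  # not-found is NULL, corruption is an error
  expect_null(load_cached_ranking(tempfile(), cfg))
  writeLines("gene_name,bogus", path)
  expect_error(load_cached_ranking(folder, cfg), "delete")
})
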