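# Subset search: enumeration, subset-derived seeding, greedy/beam/swap
# behavior, and scheduling invariance.

test_that("subset enumeration counts and order", {
  s5 <- enumerate_subsets(letters[1:5])
  expect_length(s5, 31)
  expect_length(enumerate_subsets("a"), 1)
  expect_length(enumerate_subsets(letters[1:10]), 1023)
  # ordered by size then lexicographic candidate position
  expect_identical(s5[[1]], "a")
  expect_identical(s5[[6]], c("a", "b"))
  expect_identical(s5[[31]], letters[1:5])
  expect_false(anyDuplicated(vapply(s5, paste, character(1), collapse = "+")) > 0)
})

test_that("exhaustive enumeration refuses pools beyond the million-subset cap", {
  expect_error(enumerate_subsets(paste0("g", 1:20)), "greedy")
  expect_silent(invisible(enumerate_subsets(paste0("g", 1:10))))
})

test_that("subset seeds are order-invariant, stable, and in integer range", {
  s1 <- subset_seed(c("INS", "GCG"), 7)
  s2 <- subset_seed(c("GCG", "INS"), 7)
  expect_identical(s1, s2)
  expect_false(subset_seed(c("INS"), 7) == s1)
  expect_false(subset_seed(c("INS", "GCG"), 8) == s1)
  expect_true(s1 >= 0 && s1 < 2^31)
})

# A compact pool around one perfect marker: exhaustive search is cheap
# and acts as its own oracle for greedy and swap behavior.
search_fixture <- function() separable_fixture(n_per_group = 50, n_noise = 4, seed = 21)
search_run_cfg <- function() run_config(number_sweeps = 3, base_seed = 11)

test_that("exhaustive search finds the marker in every top subset", {
  d <- search_fixture()
  r <- rank_genes(d)
  cfg <- search_config(top_n_genes = 5, num_threads = 1)
  map <- run_explorative_gene_selections(d, r, cfg, search_run_cfg())
  expect_s3_class(map, "subset_map")
  expect_length(map, 31)
  scores <- vapply(map, function(e) summary(e)$mean_test_balanced_accuracy,
                   numeric(1))
  with_marker <- grepl("\\bmarker\\b", names(map))
  # every marker-containing subset outperforms every marker-free one
  expect_gt(min(scores[with_marker]), max(scores[!with_marker]))
  expect_lte(max(scores[!with_marker]), 0.65)
})

test_that("greedy picks the marker first and its trace is nested", {
  d <- search_fixture()
  r <- rank_genes(d)
  cfg <- search_config(top_n_genes = 5, greedy_threshold = 2, num_threads = 1)
  map <- run_greedy_selection(d, r, cfg, search_run_cfg())
  keys <- names(map)
  sizes <- vapply(strsplit(keys, "+", fixed = TRUE), length, integer(1))
  # depth-1 evaluations include all 5 singletons; best singleton is the marker
  singles <- keys[sizes == 1]
  expect_setequal(singles, r$gene_name[1:5])
  s1 <- vapply(map[singles], function(e) summary(e)$mean_test_balanced_accuracy,
               numeric(1))
  expect_equal(names(which.max(s1)), "marker")
})

test_that("greedy switches on automatically above the threshold", {
  d <- search_fixture()
  r <- rank_genes(d)
  cfg <- search_config(top_n_genes = 5, greedy_threshold = 4, num_threads = 1)
  map <- run_explorative_gene_selections(d, r, cfg, search_run_cfg())
  expect_lt(length(map), 31)   # greedy trace, not full enumeration
})

test_that("greedy never beats the exhaustive optimum and shares evaluations", {
  d <- search_fixture()
  r <- rank_genes(d)
  run_cfg <- search_run_cfg()
  ex <- run_explorative_gene_selections(d, r, search_config(top_n_genes = 5),
                                        run_cfg)
  gr <- run_greedy_selection(d, r, search_config(top_n_genes = 5,
                                                 greedy_threshold = 2),
                             run_cfg)
  score <- function(map) vapply(map, function(e)
    summary(e)$mean_test_balanced_accuracy, numeric(1))
  expect_gte(max(score(ex)), max(score(gr)))
  shared <- intersect(names(ex), names(gr))
  expect_gt(length(shared), 0)
  for (k in shared) expect_identical(ex[[k]]$sweeps, gr[[k]]$sweeps)
})

test_that("beam width 1 without swaps equals plain greedy; wider beams do not lose", {
  d <- search_fixture()
  r <- rank_genes(d)
  run_cfg <- search_run_cfg()
  g1 <- run_greedy_selection(d, r, search_config(top_n_genes = 5, beam_width = 1),
                             run_cfg)
  g1b <- run_greedy_selection(d, r, search_config(top_n_genes = 5, beam_width = 1,
                                                  allow_swaps = FALSE),
                              run_cfg)
  expect_identical(names(g1), names(g1b))
  g3 <- run_greedy_selection(d, r, search_config(top_n_genes = 5, beam_width = 3),
                             run_cfg)
  score <- function(map) max(vapply(map, function(e)
    summary(e)$mean_test_balanced_accuracy, numeric(1)))
  expect_gte(score(g3), score(g1))
})

test_that("improvement tolerance 1 stops the greedy search after one gene", {
  d <- search_fixture()
  r <- rank_genes(d)
  map <- run_greedy_selection(d, r, search_config(top_n_genes = 5,
                                                  improvement_tolerance = 1),
                              search_run_cfg())
  sizes <- vapply(strsplit(names(map), "+", fixed = TRUE), length, integer(1))
  expect_equal(max(sizes), 1)
})

test_that("swap refinement replaces a noise gene by the marker", {
  d <- search_fixture()
  refined <- swap_refinement("noise_1", c("marker"), d,
                             run_cfg = search_run_cfg())
  expect_identical(refined, "marker")
  # already-optimal panel is returned unchanged
  same <- swap_refinement("marker", c("noise_1", "noise_2"), d,
                          run_cfg = search_run_cfg())
  expect_identical(same, "marker")
  expect_identical(swap_refinement(c("marker"), character(0), d), "marker")
  expect_error(swap_refinement(character(0), "marker", d), "non-empty")
})

test_that("custom-set exploration is exhaustive regardless of threshold", {
  d <- search_fixture()
  map <- run_explorative_with_custom_set(d, c("marker", "noise_1", "noise_2"),
                                         search_config(greedy_threshold = 1),
                                         search_run_cfg())
  expect_length(map, 7)
  # singleton evaluation equals the direct custom-set run (same derived seed)
  single <- map[["marker"]]
  rc <- search_run_cfg()
  rc$base_seed <- subset_seed("marker", rc$base_seed)
  direct <- run_with_custom_gene_set(d, "marker", cfg = rc)[[1]]
  expect_identical(single$sweeps, direct$sweeps)
  # supersets of the marker never fall far below its singleton accuracy
  score <- vapply(map, function(e) summary(e)$mean_test_balanced_accuracy,
                  numeric(1))
  expect_gte(max(score), score[["marker"]] - 0.05)
})

test_that("results are invariant to the thread count", {
  d <- search_fixture()
  r <- rank_genes(d)
  run_cfg <- search_run_cfg()
  m1 <- run_explorative_gene_selections(d, r, search_config(top_n_genes = 3,
                                                            num_threads = 1),
                                        run_cfg)
  m2 <- run_explorative_gene_selections(d, r, search_config(top_n_genes = 3,
                                                            num_threads = 4),
                                        run_cfg)
  expect_identical(names(m1), names(m2))
  for (k in names(m1)) expect_identical(m1[[k]]$sweeps, m2[[k]]$sweeps)
})
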