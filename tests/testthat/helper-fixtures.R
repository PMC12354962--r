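# Shared fixture builders. Everything is generated in code; tests never
# read stored binary data.

# Tiny deterministic labeled matrix with hand-set values.
tiny_matrix <- function() {
  v <- matrix(c(0, 1, 2, 3,
                5, 5, 5, 5,
                2, 4, 6, 8), nrow = 4,
              dimnames = list(paste0("s", 1:4), c("gA", "gB", "gC")))
  labeled_matrix(v, c(0, 0, 1, 1))
}

# One perfectly separating gene among label-independent noise genes.
# The separator takes value 0 for class 0 and 10 for class 1.
separable_fixture <- function(n_per_group = 100, n_noise = 49, seed = 11) {
  withr::with_seed(seed, {
    n <- 2 * n_per_group
    labels <- rep(c(0L, 1L), each = n_per_group)
    X <- matrix(rnorm(n * n_noise), nrow = n)
    X <- cbind(ifelse(labels == 1L, 10, 0) + rnorm(n, sd = 0.1), X)
    colnames(X) <- c("marker", paste0("noise_", seq_len(n_noise)))
    labeled_matrix(X, labels)
  })
}

# Labels drawn independently of all genes: pure chance-level data.
shuffled_fixture <- function(n_per_group = 100, n_genes = 20, seed = 5) {
  withr::with_seed(seed, {
    n <- 2 * n_per_group
    X <- matrix(rnorm(n * n_genes), nrow = n,
                dimnames = list(NULL, paste0("g", seq_len(n_genes))))
    labeled_matrix(X, sample(rep(c(0L, 1L), each = n_per_group)))
  })
}

# Fast run configuration for tests that only need structural behavior.
fast_cfg <- function(...) {
  run_config(number_sweeps = 3L, max_iterations = 100L, base_seed = 1L, ...)
}

# Brute-force MI oracle: literal double sum over a joint count table,
# independent of the package's implementation path.
mi_oracle <- function(bins, labels, log_base = 2) {
  n <- length(bins)
  ub <- sort(unique(bins)); ul <- sort(unique(labels))
  total <- 0
  for (b in ub) {
    for (l in ul) {
      pxy <- sum(bins == b & labels == l) / n
      if (pxy > 0) {
        px <- sum(bins == b) / n
        py <- sum(labels == l) / n
        total <- total + pxy * log(pxy / (px * py), base = log_base)
      }
    }
  }
  total
}
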