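# shared fixtures and small oracles for the test suite

# small, fast section config used by most unit tests
small_config <- function(seed = 1, ...) {
  synthetic_config(n_rows = 20, n_cols = 24, n_marker_genes_per_domain = 10,
                   n_gradient_genes_per_class = 15, n_noise_genes = 120,
                   module_spec = list(
                     BMP = list(n = 15, peak = 0.30, genotype_multiplier = 0),
                     MAPK = list(n = 15, peak = 0.15, genotype_multiplier = 2)),
                   seed = seed, ...)
}

# default-scale section for recovery tests (2,000 spots)
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_section(synthetic_config(seed = 1),
                                                   "control")
    cache
  }
})

# adjusted Rand index, computed directly from the contingency table
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# brute-force running-sum enrichment oracle: explicit prefix walk
es_bruteforce <- function(metric, hit, weight = 1) {
  n <- length(metric)
  denom <- sum(abs(metric[hit])^weight)
  run <- 0
  best <- 0
  for (i in seq_len(n)) {
    run <- run + if (hit[i]) abs(metric[i])^weight / denom else -1 / (n - sum(hit))
    if (abs(run) > abs(best)) best <- run
  }
  best
}
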