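# Small fixtures built in code, shared across test files.

# tiny labeled table with known values
toy_table <- function() {
  tibble::tibble(mw = c(200, 650, 1100, 500),
                 logp = c(-2, 3, 8, 1),
                 tpsa = c(20, 60, 140, 80),
                 label = c(1L, 1L, 0L, 1L))
}

# small synthetic dataset for fast model tests
small_spec <- function(seed = 42, ...) {
  synthetic_spec(n_train = 60, n_test = 30, n_success = 40, n_failure = 20,
                 n_features = 12, n_informative = 4, seed = seed, ...)
}

# two well-separated pure clusters in 2-D (labels match clusters)
separated_clusters <- function(n_per = 20, gap = 50, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per * 2), n_per, 2),
               matrix(rnorm(n_per * 2, mean = gap), n_per, 2))
    tibble::tibble(f1 = x[, 1], f2 = x[, 2],
                   label = rep(c(0L, 1L), each = n_per))
  })
}
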