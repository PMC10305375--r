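make_nopca_fit <- function(seed = 1, class_separation = 5) {
  ds <- simulate_formulations(small_spec(seed = seed,
                                         class_separation = class_separation))
  fit <- plc_fit(ds$train, augment = "none", use_pca = FALSE,
                 vae_iterations = 50, cnn_iterations = 600, seed = seed)
  list(ds = ds, fit = fit)
}

test_that("scores are normalized, ranked, and zero for constant columns", {
  obj <- make_nopca_fit(seed = 2)
  rep <- permutation_importance(obj$fit, obj$ds$train, n_repeats = 3,
                                seed = 4)
  expect_s3_class(rep, "plc_importance")
  expect_equal(sum(rep$score), 1, tolerance = 1e-9)
  expect_true(all(diff(rep$score) <= 1e-12))
  expect_identical(rep$rank, seq_len(nrow(rep)))
  const <- grep("heavy_atoms", rep$feature)
  expect_equal(rep$score[const], 0)
  expect_true("group" %in% names(rep))
})

test_that("a single-signal feature ranks first with a dominant score", {
  # one informative feature carries all class signal
  spec <- synthetic_spec(n_train = 120, n_test = 30, n_success = 60,
                         n_failure = 60, n_features = 6, n_informative = 1,
                         class_separation = 6, n_constant = 0,
                         feature_scales = NULL, seed = 3)
  ds <- simulate_formulations(spec)
  fit <- plc_fit(ds$train, augment = "none", use_pca = FALSE,
                 cnn_iterations = 800, seed = 3)
  rep <- permutation_importance(fit, ds$train, n_repeats = 5, seed = 5)
  expect_equal(rep$feature[1], names(ds$train)[1])
  expect_gt(rep$score[1], 0.5)

  # ranking of the top feature is stable in the number of repeats
  rep1 <- permutation_importance(fit, ds$train, n_repeats = 1, seed = 6)
  rep2 <- permutation_importance(fit, ds$train, n_repeats = 20, seed = 6)
  expect_identical(rep1$feature[1], rep2$feature[1])
})

test_that("a model that ignores everything scores exactly zero everywhere", {
  ds <- simulate_formulations(small_spec(seed = 7))
  xn <- apply_minmax(fit_minmax(ds$train), ds$train)
  model <- build_cnn(cnn_architecture(input_length = 12), seed = 1)
  model$params <- lapply(model$params, function(p) p * 0)
  fit <- list(model = model,
              history = tibble::tibble(iteration = 1L, loss = 0,
                                       accuracy = 0),
              config = list(), features = setdiff(names(xn), "label"))
  class(fit) <- "plc_cnn_fit"
  rep <- permutation_importance(fit, xn, n_repeats = 2, seed = 8)
  expect_equal(attr(rep, "raw_drops"), rep(0, 12))
  expect_equal(rep$score, rep(0, 12))
})

test_that("importance is invariant under descriptor renaming and reports top-k", {
  obj <- make_nopca_fit(seed = 9)
  rep <- permutation_importance(obj$fit, obj$ds$train, n_repeats = 2,
                                seed = 10)
  renamed <- obj$ds$train
  names(renamed) <- c(paste0("q", seq_len(ncol(renamed) - 1)), "label")
  # same data, same model; only names differ
  fit2 <- obj$fit
  fit2$norm$feature <- setdiff(names(renamed), "label")
  fit2$cnn$features <- setdiff(names(renamed), "label")
  rep2 <- permutation_importance(fit2, renamed, n_repeats = 2, seed = 10)
  expect_equal(rep$score, rep2$score)

  top <- top_descriptors(rep, 5)
  expect_equal(nrow(top), 5L)
  expect_identical(top$feature, rep$feature[1:5])
  expect_identical(top_descriptors(rep, nrow(rep)), rep)
  expect_identical(top_descriptors(rep, 1)$feature,
                   rep$feature[which.max(rep$score)])
  expect_error(top_descriptors(rep, 0), class = "plc_error_bad_k")
})

test_that("a PCA pipeline is rejected for per-descriptor attribution", {
  ds <- simulate_formulations(small_spec(seed = 11))
  fit <- plc_fit(ds$train, augment = "none", use_pca = TRUE,
                 n_components = 6, cnn_iterations = 30, seed = 2)
  expect_error(permutation_importance(fit, ds$train, n_repeats = 1),
               class = "plc_error_pca_fit")
})
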