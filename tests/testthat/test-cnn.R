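test_that("the default architecture traces 10 -> 5 -> 2 and counts 2081 parameters", {
  arch <- cnn_architecture()
  model <- build_cnn(arch, seed = 1)
  tr <- model$trace
  expect_equal(tr$conv, c(10L, 10L, 10L))   # kernel/stride 1 preserve length
  expect_equal(tr$skip, 10L)
  expect_equal(tr$skip_channels, 40L)
  expect_equal(tr$pool1, 5L)
  expect_equal(tr$conv4, 5L)
  expect_equal(tr$pool2, 2L)
  expect_equal(tr$flatten, 64L)
  # (1*8+8) + (8*16+16) + (16*32+32) + (40*32+32) + (64+1)
  expect_equal(model$n_parameters, 2081L)
  expect_equal(cnn_parameter_count(arch), 2081L)
  # parameter count is a pure function of the architecture
  expect_equal(build_cnn(arch, seed = 99)$n_parameters, 2081L)
})

test_that("architecture validation catches bad configurations", {
  expect_error(cnn_architecture(conv_channels = c(8, 8, 32)),
               class = "plc_error_bad_arch")
  expect_error(cnn_architecture(input_length = 3),
               class = "plc_error_bad_arch")
  expect_error(cnn_architecture(kernel_size = 0),
               class = "plc_error_bad_arch")
})

test_that("forward pass maps into (0, 1); zero weights give exactly 0.5", {
  model <- build_cnn(cnn_architecture(), seed = 2)
  withr::with_seed(3, x <- matrix(rnorm(50), 5, 10))
  p <- cnn_forward(model, x)
  expect_length(p, 5)
  expect_true(all(p > 0 & p < 1))
  m0 <- model
  m0$params <- lapply(m0$params, function(q) q * 0)
  expect_equal(cnn_forward(m0, x), rep(0.5, 5))
  expect_error(cnn_forward(model, matrix(0, 2, 7)),
               class = "plc_error_dim_mismatch")
})

test_that("batched forward equals per-row forward and is batch-order equivariant", {
  model <- build_cnn(cnn_architecture(), seed = 4)
  withr::with_seed(5, x <- matrix(rnorm(120), 12, 10))
  pb <- cnn_forward(model, x)
  p1 <- vapply(seq_len(12), function(i) cnn_forward(model, x[i, ]),
               numeric(1))
  expect_equal(pb, p1, tolerance = 1e-6)
  perm <- c(7, 1, 12, 3, 5, 9, 2, 11, 8, 4, 10, 6)
  expect_equal(cnn_forward(model, x[perm, ]), pb[perm], tolerance = 1e-12)
})

test_that("training descends, logs histories, and is bit-reproducible", {
  ds <- simulate_formulations(small_spec(seed = 1))
  xn <- apply_minmax(fit_minmax(ds$train), ds$train)
  red <- pca_transform(fit_pca(xn), xn, k = 10)
  f1 <- train_cnn(NULL, red, iterations = 400, seed = 6)
  f2 <- train_cnn(NULL, red, iterations = 400, seed = 6)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
  sm <- function(v) mean(v)
  expect_lt(mean(tail(f1$history$loss, 100)), mean(head(f1$history$loss, 100)))
  expect_equal(nrow(f1$history), 400L)

  bad <- red; bad$label <- bad$label + 2L
  expect_error(train_cnn(NULL, bad, iterations = 2),
               class = "plc_error_label_levels")
})

test_that("compiled and R training engines match", {
  ds <- simulate_formulations(small_spec(seed = 2))
  xn <- apply_minmax(fit_minmax(ds$train), ds$train)
  red <- pca_transform(fit_pca(xn), xn, k = 8)
  a <- train_cnn(NULL, red, iterations = 40, seed = 3, engine = "r")
  b <- train_cnn(NULL, red, iterations = 40, seed = 3, engine = "cpp")
  expect_equal(a$history$loss, b$history$loss, tolerance = 1e-10)
  expect_equal(a$model$params, b$model$params, tolerance = 1e-10)
})

test_that("engines also agree for kernel > 1, stride > 1 and average pooling", {
  ds <- simulate_formulations(small_spec(seed = 5))
  xn <- apply_minmax(fit_minmax(ds$train), ds$train)
  arch <- cnn_architecture(input_length = 12, kernel_size = 2,
                           pool = "average")
  a <- train_cnn(build_cnn(arch, seed = 8), xn,
                 iterations = 30, seed = 8, engine = "r")
  b <- train_cnn(build_cnn(arch, seed = 8), xn,
                 iterations = 30, seed = 8, engine = "cpp")
  expect_equal(a$history$loss, b$history$loss, tolerance = 1e-10)
})

test_that("a separable problem is learned to high training accuracy", {
  spec <- small_spec(seed = 9, class_separation = 6)
  ds <- simulate_formulations(spec)
  expect_gte(ds$bayes_accuracy, 0.97)
  xn <- apply_minmax(fit_minmax(ds$train), ds$train)
  red <- pca_transform(fit_pca(xn), xn, k = 6)
  fit <- train_cnn(NULL, red, iterations = 1200, seed = 10)
  expect_gte(fit$history$accuracy[1200], 0.9)
})

test_that("prediction applies the >= threshold rule across its whole range", {
  ds <- simulate_formulations(small_spec(seed = 11))
  xn <- apply_minmax(fit_minmax(ds$train), ds$train)
  red <- pca_transform(fit_pca(xn), xn, k = 10)
  fit <- train_cnn(NULL, red, iterations = 100, seed = 12)
  pr <- predict(fit, red, threshold = 0.5)
  expect_identical(pr$.pred, as.integer(pr$.prob >= 0.5))
  expect_true(all(predict(fit, red, threshold = 0)$.pred == 1L))
  expect_true(all(predict(fit, red, threshold = 1)$.pred == 0L))
})
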