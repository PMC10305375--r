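test_that("default spec reproduces the study's split shape", {
  ds <- simulate_formulations(synthetic_spec(seed = 11))
  cc <- class_counts(ds$train)
  expect_equal(cc$n_success, 179L)
  expect_equal(cc$n_failure, 93L)
  expect_equal(nrow(ds$test), 69L)
  expect_equal(ncol(ds$train) - 1L, 46L)
  expect_identical(names(ds$train), names(ds$test))
})

test_that("generation is deterministic per seed and distinct across seeds", {
  a <- simulate_formulations(synthetic_spec(seed = 5))
  b <- simulate_formulations(synthetic_spec(seed = 5))
  c <- simulate_formulations(synthetic_spec(seed = 6))
  expect_identical(a$train, b$train)
  expect_identical(a$test, b$test)
  expect_false(identical(a$train, c$train))
})

test_that("constant features have exactly zero variance in both splits", {
  ds <- simulate_formulations(synthetic_spec(seed = 3, n_constant = 2))
  const_cols <- grep("heavy_atoms", names(ds$train), value = TRUE)
  expect_length(const_cols, 2L)
  for (cl in const_cols) {
    expect_equal(var(ds$train[[cl]]), 0)
    expect_true(all(ds$train[[cl]] == 52), all(ds$test[[cl]] == 52))
  }
})

test_that("sample ranges fall inside the configured scale intervals", {
  ds <- simulate_formulations(synthetic_spec(seed = 9))
  sc <- default_feature_scales(46)
  both <- dplyr::bind_rows(ds$train, ds$test)
  # constant column sits outside the scale table's reach
  for (j in 1:45) {
    v <- both[[j]]
    expect_gte(min(v), sc$offset[j] - 1e-9)
    expect_lte(max(v), sc$offset[j] + sc$range[j] + 1e-9)
  }
  expect_gte(min(both[[1]]), 200); expect_lte(max(both[[1]]), 1100)
  expect_gte(min(both[[2]]), -2); expect_lte(max(both[[2]]), 8)
})

test_that("Bayes oracle matches the closed form and its limits", {
  eq <- function(d) synthetic_spec(n_train = 200, n_success = 100,
                                   n_failure = 100, class_separation = d)
  expect_equal(bayes_accuracy(eq(0)), 0.5)
  expect_equal(bayes_accuracy(eq(2)), pnorm(1))
  expect_equal(bayes_accuracy(eq(60)), 1.0, tolerance = 1e-12)
  # no signal -> larger prior
  expect_equal(bayes_accuracy(synthetic_spec(class_separation = 0)), 179 / 272)
})

test_that("analytic LDA rule on 50k generated points attains the oracle accuracy", {
  d <- 2; m <- 4; rho <- 0.7
  spec <- synthetic_spec(n_train = 50000, n_test = 10,
                         n_success = 25000, n_failure = 25000,
                         n_features = m, n_informative = m,
                         class_separation = d, informative_correlation = rho,
                         n_constant = 0, feature_scales = NULL, seed = 21)
  ds <- simulate_formulations(spec)
  x <- as.matrix(ds$train[, 1:m])
  y <- ds$train$label
  # shared covariance sigma^2[(1-rho)I + rho J]; shift c on every feature
  shift <- d * sqrt((1 - rho + rho * m) / m)
  sigma <- (1 - rho) * diag(m) + rho * matrix(1, m, m)
  w <- solve(sigma, rep(shift, m))
  mid <- rep(shift / 2, m)
  pred <- as.integer(x %*% w > sum(w * mid))
  acc <- mean(pred == y)
  expected <- pnorm(d / 2)
  se <- sqrt(expected * (1 - expected) / nrow(x))
  expect_lt(abs(acc - expected), 3 * se)
})

test_that("infeasible specs are rejected", {
  expect_error(synthetic_spec(n_train = 10, n_success = 5, n_failure = 4),
               class = "plc_error_infeasible_spec")
  expect_error(synthetic_spec(n_features = 5, n_informative = 6,
                              n_train = 272),
               class = "plc_error_infeasible_spec")
  expect_error(synthetic_spec(class_separation = -1),
               class = "plc_error_infeasible_spec")
})
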