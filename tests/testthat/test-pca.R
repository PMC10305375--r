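test_that("first component recovers a planted principal axis", {
  withr::with_seed(5, {
    t <- rnorm(4000, sd = 3)
    x <- cbind(t / sqrt(2), t / sqrt(2)) + matrix(rnorm(8000, sd = 0.05),
                                                  ncol = 2)
  })
  tbl <- tibble::tibble(a = x[, 1], b = x[, 2], label = rep(0L, 4000))
  model <- fit_pca(tbl)
  v1 <- model$components[, 1]
  target <- c(1, 1) / sqrt(2)
  angle <- acos(min(1, abs(sum(v1 * target))))
  expect_lt(angle, 1e-3)
})

test_that("isotropic data explains variance evenly; constant columns contribute zero", {
  withr::with_seed(6, x <- matrix(rnorm(2e5), ncol = 2))
  tbl <- tibble::tibble(a = x[, 1], b = x[, 2])
  model <- fit_pca(tbl, label = "none")
  expect_equal(model$explained_variance_ratio, c(0.5, 0.5), tolerance = 0.01)

  tbl$c <- 52
  m2 <- fit_pca(tbl, label = "none")
  expect_equal(m2$eigenvalues[3], 0, tolerance = 1e-12)
})

test_that("fitted models satisfy the orthonormality and variance-conservation invariants", {
  withr::with_seed(7, {
    for (rep in 1:5) {
      x <- matrix(rnorm(8 * 5), 8, 5) * rep(10^(-1:3), each = 8)
      tbl <- tibble::as_tibble(as.data.frame(x))
      model <- fit_pca(tbl, label = "none")
      p <- ncol(x)
      expect_equal(crossprod(model$components), diag(p), tolerance = 1e-8)
      expect_true(all(diff(model$eigenvalues) <= 1e-12))
      expect_equal(sum(model$eigenvalues), sum(diag(cov(x))),
                   tolerance = 1e-8)
      # brute-force oracle: dense symmetric eigendecomposition of cov(x)
      ev <- eigen(cov(x), symmetric = TRUE)$values
      expect_equal(model$eigenvalues, ev, tolerance = 1e-8)
    }
  })
})

test_that("scree table cumulates to 1 and select_components applies the 85% rule", {
  ds <- simulate_formulations(small_spec(seed = 3))
  model <- fit_pca(apply_minmax(fit_minmax(ds$train), ds$train))
  sc <- pca_scree(model)
  expect_true(all(diff(sc$cumulative) >= -1e-12))
  expect_equal(sc$cumulative[nrow(sc)], 1, tolerance = 1e-9)
  expect_true(all(diff(sc$eigenvalue) <= 1e-12))

  fake <- model
  fake$eigenvalues <- c(0.5, 0.3, 0.15, 0.05)
  fake$explained_variance_ratio <- fake$eigenvalues
  fake$feature <- paste0("f", 1:4)
  expect_equal(pca_scree(fake)$cumulative, c(0.5, 0.8, 0.95, 1))
  expect_equal(select_components(fake), 3L)        # 0.8 < 0.85 <= 0.95
  expect_equal(select_components(fake, fixed_k = 2), 2L)
  expect_equal(select_components(fake, cumulative_threshold = 1), 4L)
  expect_error(select_components(fake, fixed_k = 9),
               class = "plc_error_bad_k")
})

test_that("projection keeps labels, reduces width, and inverts at full rank", {
  ds <- simulate_formulations(synthetic_spec(seed = 2))
  xn <- apply_minmax(fit_minmax(ds$train), ds$train)
  model <- fit_pca(xn)
  red <- pca_transform(model, xn, k = 10)
  expect_equal(ncol(red), 11L)
  expect_identical(red$label, xn$label)
  expect_identical(names(red)[1:10], paste0("PC", 1:10))

  full <- pca_transform(model, xn, k = 46)
  back <- pca_inverse(model, full)
  expect_equal(as.matrix(back[1:46]), as.matrix(xn[1:46]), tolerance = 1e-8)

  # training scores: per-column variance equals the eigenvalue, uncorrelated
  scores <- as.matrix(full[1:46])
  expect_equal(unname(apply(scores, 2, var)), model$eigenvalues,
               tolerance = 1e-6)
  cors <- cor(scores[, model$eigenvalues > 1e-10])
  expect_lt(max(abs(cors[upper.tri(cors)])), 1e-6)

  expect_error(pca_transform(model, xn, k = 0), class = "plc_error_bad_k")
  expect_error(pca_transform(model, ds$test[, -1], k = 2),
               class = "plc_error_feature_mismatch")
  expect_error(fit_pca(xn[1, ]), class = "plc_error_empty_table")
})
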