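test_that("confusion counts enumerate correctly and match a loop oracle", {
  cc <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(unlist(cc), c(tp = 1L, fp = 1L, tn = 1L, fn = 1L))
  perfect <- confusion_counts(c(1, 0, 1), c(1, 0, 1))
  expect_equal(perfect$fp + perfect$fn, 0L)

  withr::with_seed(17, {
    y <- sample(0:1, 1000, replace = TRUE)
    p <- sample(0:1, 1000, replace = TRUE)
  })
  cc <- confusion_counts(y, p)
  oracle <- c(tp = 0L, fp = 0L, tn = 0L, fn = 0L)
  for (i in seq_along(y)) {
    slot <- if (y[i] == 1 && p[i] == 1) "tp"
            else if (y[i] == 0 && p[i] == 1) "fp"
            else if (y[i] == 0 && p[i] == 0) "tn" else "fn"
    oracle[slot] <- oracle[slot] + 1L
  }
  expect_equal(unlist(cc), oracle)
  expect_equal(sum(unlist(cc)), 1000L)
  expect_error(confusion_counts(c(1, 0), c(1, 0, 1)),
               class = "plc_error_length_mismatch")
  expect_error(confusion_counts(c(1, 2), c(1, 0)),
               class = "plc_error_label_levels")
})

test_that("metric formulas are exact and undefined cases return NA", {
  m <- classification_metrics(list(tp = 3, fp = 1, tn = 4, fn = 2))
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$sensitivity, 0.6)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$precision, 0.75)
  expect_equal(m$f1, 2 / 3)

  none_pos <- classification_metrics(list(tp = 0, fp = 0, tn = 5, fn = 0))
  expect_true(is.na(none_pos$sensitivity))
  expect_true(is.na(none_pos$precision))
  perfect <- classification_metrics(list(tp = 4, fp = 0, tn = 6, fn = 0))
  expect_equal(unlist(perfect), c(accuracy = 1, sensitivity = 1,
                                  specificity = 1, precision = 1, f1 = 1))
})

test_that("metrics agree with brute-force formulas on random confusion vectors", {
  withr::with_seed(23, {
    for (rep in 1:200) {
      n <- sample(2:40, 1)
      y <- sample(0:1, n, replace = TRUE)
      p <- sample(0:1, n, replace = TRUE)
      m <- classification_metrics(confusion_counts(y, p))
      expect_equal(m$accuracy, mean(y == p))
      if (sum(y == 1) > 0) {
        expect_equal(m$sensitivity, sum(y == 1 & p == 1) / sum(y == 1))
      }
      if (!is.na(m$precision) && !is.na(m$sensitivity) &&
          m$precision + m$sensitivity > 0) {
        expect_equal(m$f1, 2 * m$precision * m$sensitivity /
                       (m$precision + m$sensitivity))
      }
    }
  })
})

test_that("AUC equals the pairwise probability oracle and its limits", {
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.3, 4)), 0.5)
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1.0)

  pairwise_auc <- function(y, s) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(pos) * length(neg))
  }
  withr::with_seed(29, {
    for (rep in 1:50) {
      n <- 12
      y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
      s <- round(rnorm(n), 1)  # induce ties
      expect_equal(roc_auc(y, s), pairwise_auc(y, s), tolerance = 1e-12)
    }
  })
  expect_error(roc_auc(rep(1, 4), rnorm(4)), class = "plc_error_single_class")
})

test_that("AUC is invariant under monotone transforms and complements under negation", {
  withr::with_seed(31, {
    y <- c(0, 1, sample(0:1, 20, replace = TRUE))
    s <- rnorm(22)  # continuous, tie-free
  })
  a <- roc_auc(y, s)
  expect_equal(roc_auc(y, exp(s)), a)
  expect_equal(roc_auc(y, 5 * s - 2), a)
  expect_equal(roc_auc(y, s) + roc_auc(y, -s), 1)
})

test_that("metric_row assembles the report column set", {
  row <- metric_row(c(1, 0, 1, 1), c(1, 0, 0, 1), c(0.9, 0.2, 0.4, 0.8))
  expect_named(row, c("accuracy", "auc", "specificity", "sensitivity",
                      "f1", "precision"))
  expect_equal(row$accuracy, 0.75)
  expect_equal(row$auc, 1)
})
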