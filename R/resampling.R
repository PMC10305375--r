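#' SMOTE: synthetic minority oversampling
#'
#' Balances the classes by interpolation: each synthetic row is
#' `x + u * (x' - x)` where `x` is a uniformly drawn minority row, `x'`
#' one of its `k` nearest minority neighbours (Euclidean distance in the
#' normalized feature space) and `u ~ Uniform(0, 1)`. Exactly
#' `n_majority - n_minority` rows are generated, so the output is
#' balanced; all original rows are kept untouched.
#'
#' @param data Descriptor table with a binary label (normalize first so
#'   distances are not dominated by large-unit columns).
#' @param k Number of minority nearest neighbours (default 5); the
#'   minority class must contain more than `k` rows.
#' @param seed Integer seed.
#' @param label Label column name.
#' @return A balanced descriptor tibble with attribute `"origin"`
#'   (`"original"` / `"generated"`).
#' @export
smote <- function(data, k = 5, seed = 1, label = "label") {
  parts <- table_parts(data, label = label)
  counts <- class_counts(data, label = label)
  minority_lab <- if (counts$n_success < counts$n_failure) 1L else 0L
  n_min <- min(counts$n_success, counts$n_failure)
  gap <- abs(counts$n_success - counts$n_failure)
  if (n_min <= k) {
    abort(sprintf("Minority class has %d rows; SMOTE with k = %d needs more than k.",
                  n_min, k),
          class = "plc_error_too_few_minority")
  }
  orig <- rebuild_table(parts$x, parts$y, parts$features, label = label)
  if (gap == 0L) {
    attr(orig, "origin") <- rep("original", nrow(orig))
    return(orig)
  }
  xm <- parts$x[parts$y == minority_lab, , drop = FALSE]
  d <- as.matrix(dist(xm))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(row) order(row)[seq_len(k)]))
  synth <- with_seed(seed, {
    base <- sample.int(nrow(xm), gap, replace = TRUE)
    pickn <- sample.int(k, gap, replace = TRUE)
    u <- runif(gap)
    xb <- xm[base, , drop = FALSE]
    xn <- xm[nn[cbind(base, pickn)], , drop = FALSE]
    xb + u * (xn - xb)
  })
  out <- dplyr::bind_rows(orig,
                          rebuild_table(synth, rep(minority_lab, gap),
                                        parts$features, label = label))
  attr(out, "origin") <- rep(c("original", "generated"), c(nrow(orig), gap))
  out
}

#' ENN: edited nearest-neighbour undersampling
#'
#' Removes every row whose label disagrees with the strict majority label
#' of its `k` nearest neighbours (Euclidean, excluding the row itself).
#' When the neighbourhood vote is tied, the row is kept. Editing only
#' deletes: the output is a subset of the input rows.
#'
#' @param data Descriptor table with a binary label.
#' @param k Neighbourhood size (default 3).
#' @param label Label column name.
#' @return The edited descriptor tibble.
#' @export
enn <- function(data, k = 3, label = "label") {
  parts <- table_parts(data, label = label)
  n <- nrow(parts$x)
  if (n <= k) {
    abort(sprintf("ENN with k = %d needs more than k rows (got %d).", k, n),
          class = "plc_error_too_few_rows")
  }
  d <- as.matrix(dist(parts$x))
  diag(d) <- Inf
  keep <- vapply(seq_len(n), function(i) {
    nb <- order(d[i, ])[seq_len(k)]
    disagree <- sum(parts$y[nb] != parts$y[i])
    disagree <= k / 2  # removed only on strict majority disagreement
  }, logical(1))
  out <- rebuild_table(parts$x[keep, , drop = FALSE], parts$y[keep],
                       parts$features, label = label)
  out
}

#' SMOTE-ENN combined resampling
#'
#' Sequential composition: oversample with [smote()], then edit the result
#' with [enn()]. The edited set is never larger than the SMOTE output.
#'
#' @inheritParams smote
#' @param smote_k Neighbours for the SMOTE stage (default 5).
#' @param enn_k Neighbours for the ENN stage (default 3).
#' @return The resampled descriptor tibble.
#' @export
smote_enn <- function(data, smote_k = 5, enn_k = 3, seed = 1,
                      label = "label") {
  enn(smote(data, k = smote_k, seed = seed, label = label),
      k = enn_k, label = label)
}
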