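#' Permutation importance of molecular descriptors
#'
#' Quantifies each descriptor's predictive contribution on a pipeline
#' trained *without* PCA (component mixing would make per-descriptor
#' attribution meaningless). The score of descriptor `j` is the mean drop
#' in accuracy over `n_repeats` random permutations of column `j`,
#' floored at zero and normalized so all scores sum to one. Constant
#' columns cannot change the predictions and score exactly zero.
#'
#' @param fit A `"plc_fit"` trained with `use_pca = FALSE`, or a
#'   `"plc_cnn_fit"` trained directly on normalized descriptors.
#' @param data Labeled descriptor table to permute (typically the raw
#'   training split for a `"plc_fit"`, or a normalized table for a bare
#'   classifier fit).
#' @param n_repeats Permutations per descriptor (default 10).
#' @param seed Integer seed.
#' @param label Label column name.
#' @return A tibble of class `"plc_importance"`: `feature`, `group` (if
#'   the table carries a `"groups"` attribute), `score`, `rank`, plus a
#'   `baseline_accuracy` attribute. Ties rank by original column order.
#' @export
permutation_importance <- function(fit, data, n_repeats = 10, seed = 1,
                                   label = "label") {
  stopifnot(n_repeats >= 1)
  if (inherits(fit, "plc_fit")) {
    if (!is.null(fit$pca)) {
      abort("Importance requires a pipeline trained without PCA (use_pca = FALSE).",
            class = "plc_error_pca_fit")
    }
    predict_fun <- function(tbl) predict(fit, tbl)$.pred
  } else if (inherits(fit, "plc_cnn_fit") || inherits(fit, "plc_cnn")) {
    model <- as_cnn_model(fit)
    predict_fun <- function(tbl) {
      as.integer(cnn_forward(model, tbl, label = label) >= 0.5)
    }
  } else {
    abort("`fit` must be a 'plc_fit' (no PCA) or a 'plc_cnn_fit'.",
          class = "plc_error_bad_model")
  }
  parts <- table_parts(data, label = label)
  if (inherits(fit, "plc_cnn_fit") || inherits(fit, "plc_cnn")) {
    model <- as_cnn_model(fit)
    if (model$arch$input_length != ncol(parts$x)) {
      abort("Data width does not match the model input length.",
            class = "plc_error_dim_mismatch")
    }
  }
  tbl <- rebuild_table(parts$x, parts$y, parts$features, label = label)
  baseline <- mean(predict_fun(tbl) == parts$y)
  n <- nrow(tbl)
  drops <- with_seed(seed, {
    vapply(seq_along(parts$features), function(j) {
      mean(vapply(seq_len(n_repeats), function(r) {
        perm <- tbl
        perm[[j]] <- perm[[j]][sample.int(n)]
        baseline - mean(predict_fun(perm) == parts$y)
      }, numeric(1)))
    }, numeric(1))
  })
  score <- pmax(drops, 0)
  total <- sum(score)
  if (total > 0) score <- score / total
  ord <- order(-score, seq_along(score))
  out <- tibble(feature = parts$features, score = score)
  groups <- attr(data, "groups")
  if (!is.null(groups)) out$group <- unname(groups[out$feature])
  out$rank <- match(seq_along(score), ord)
  out <- out[ord, ]
  attr(out, "baseline_accuracy") <- baseline
  attr(out, "raw_drops") <- drops
  class(out) <- c("plc_importance", class(out))
  out
}

#' Top-k descriptors of an importance report
#'
#' @param report A `"plc_importance"` tibble.
#' @param k Number of descriptors to keep (between 1 and the number of
#'   features); a report typically shows the 20 leading contributors.
#' @return The first `k` rows of the ranking.
#' @export
top_descriptors <- function(report, k) {
  stopifnot(inherits(report, "plc_importance"))
  if (k < 1 || k > nrow(report)) {
    abort(sprintf("k must lie in [1, %d].", nrow(report)),
          class = "plc_error_bad_k")
  }
  report[seq_len(k), ]
}
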