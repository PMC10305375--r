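#' Fit the full complex-formation prediction pipeline
#'
#' End-to-end training on a raw descriptor table:
#' min-max normalization fitted on the training split, class balancing
#' (VAE augmentation by default, or a classic resampler), PCA fitted on
#' the balanced split with the retained dimensionality chosen by rule or
#' fixed, and the skip-connected 1D-CNN classifier. Every stage that the
#' test split passes through (normalization, PCA) is fitted on training
#' data only.
#'
#' The `augment` and `use_pca` switches double as the ablation
#' configuration: `augment = "none"` drops augmentation, and
#' `use_pca = FALSE` trains the classifier on all normalized descriptors
#' (the variant used for descriptor-importance analysis).
#'
#' @param train Raw training descriptor table with a binary label.
#' @param augment One of `"vae"`, `"smote"`, `"enn"`, `"smote_enn"`,
#'   `"none"` (default `"vae"`).
#' @param use_pca Reduce dimensionality before classification
#'   (default `TRUE`).
#' @param n_components Retained components: an integer (default 10, the
#'   reference configuration), or `"auto"` for the smallest k reaching
#'   85% cumulative explained variance. Values above the feature count
#'   are clamped.
#' @param n_pool VAE generation pool size (default 500).
#' @param vae_iterations,cnn_iterations Full-batch training steps
#'   (defaults 5000 and 2500).
#' @param recon_weight Weight on the VAE reconstruction loss
#'   (default 1000).
#' @param learning_rate Adam learning rate for both networks
#'   (default 0.001).
#' @param smote_k,enn_k Neighbour counts for the resampling baselines.
#' @param threshold Classification probability cut-off (default 0.5).
#' @param seed Integer seed driving every stochastic stage.
#' @param label Label column name.
#' @return An object of class `"plc_fit"` bundling the normalization
#'   parameters, the augmentation fit (for VAE), the PCA model and
#'   retained `k`, the trained classifier and the balanced training
#'   table.
#' @seealso [predict.plc_fit()], [plc_evaluate()], [compare_sampling()]
#' @export
plc_fit <- function(train,
                    augment = c("vae", "smote", "enn", "smote_enn", "none"),
                    use_pca = TRUE, n_components = 10, n_pool = 500,
                    vae_iterations = 5000, cnn_iterations = 2500,
                    recon_weight = 1000, learning_rate = 0.001,
                    smote_k = 5, enn_k = 3, threshold = 0.5, seed = 1,
                    label = "label") {
  augment <- match.arg(augment)
  norm <- fit_minmax(train, label = label)
  train_n <- apply_minmax(norm, train, label = label)

  vae <- NULL
  balanced <- switch(
    augment,
    none = train_n,
    vae = {
      vae <- train_vae(train_n, recon_weight = recon_weight,
                       learning_rate = learning_rate,
                       iterations = vae_iterations,
                       seed = child_seed(seed, 11L), label = label)
      balance_with_vae(train_n, vae, n_pool = n_pool,
                       seed = child_seed(seed, 12L), label = label)
    },
    smote = smote(train_n, k = smote_k, seed = child_seed(seed, 13L),
                  label = label),
    enn = enn(train_n, k = enn_k, label = label),
    smote_enn = smote_enn(train_n, smote_k = smote_k, enn_k = enn_k,
                          seed = child_seed(seed, 13L), label = label))

  pca <- NULL
  k <- NULL
  reduced <- balanced
  if (use_pca) {
    pca <- fit_pca(balanced, label = label)
    p <- length(pca$feature)
    k <- if (identical(n_components, "auto")) {
      select_components(pca)
    } else {
      min(as.integer(n_components), p)
    }
    reduced <- pca_transform(pca, balanced, k = k, label = label)
  }

  arch <- cnn_architecture(input_length = ncol(reduced) - 1L)
  cnn <- train_cnn(build_cnn(arch, seed = child_seed(seed, 14L)),
                   reduced, learning_rate = learning_rate,
                   iterations = cnn_iterations, threshold = threshold,
                   seed = child_seed(seed, 14L), label = label)

  structure(list(norm = norm, augment = augment, vae = vae,
                 balanced = balanced, pca = pca, k = k, cnn = cnn,
                 threshold = threshold, label = label,
                 seed = as.integer(seed)),
            class = "plc_fit")
}

#' @export
print.plc_fit <- function(x, ...) {
  cat(sprintf("<plc_fit> augment = %s; %s; %d-row balanced training set\n",
              x$augment,
              if (is.null(x$pca)) "no PCA"
              else sprintf("PCA k = %d", x$k),
              nrow(x$balanced)))
  print(x$cnn)
  invisible(x)
}

#' Predict with a fitted pipeline
#'
#' Applies the training-fitted normalization and (if configured) PCA
#' projection to `newdata`, then scores it with the trained classifier.
#'
#' @param object A `"plc_fit"`.
#' @param newdata Raw descriptor table with the training feature columns.
#' @param threshold Probability cut-off (defaults to the fit's).
#' @param ... Unused.
#' @return A tibble with `.prob` and `.pred`.
#' @export
predict.plc_fit <- function(object, newdata, threshold = NULL, ...) {
  threshold <- threshold %||% object$threshold
  x <- apply_minmax(object$norm, newdata, label = object$label)
  if (!is.null(object$pca)) {
    x <- pca_transform(object$pca, x, k = object$k, label = object$label)
  }
  predict(object$cnn, x, threshold = threshold, label = object$label)
}

#' Evaluate a fitted pipeline on a labeled table
#'
#' @param fit A `"plc_fit"`.
#' @param data Labeled descriptor table (e.g. the held-out test split).
#' @param threshold Probability cut-off (defaults to the fit's).
#' @return A one-row tibble: accuracy, AUC, specificity, sensitivity,
#'   F1, precision.
#' @export
plc_evaluate <- function(fit, data, threshold = NULL) {
  stopifnot(inherits(fit, "plc_fit"))
  parts <- table_parts(data, label = fit$label)
  pred <- predict(fit, data, threshold = threshold)
  metric_row(parts$y, pred$.pred, pred$.prob)
}

#' Compare augmentation strategies under the identical downstream pipeline
#'
#' Runs the full pipeline once per requested method — only the balancing
#' stage differs — and reports the standard metric set on the training
#' and test splits, the tabular analogue of a sampling-technique
#' comparison study.
#'
#' @param train,test Raw descriptor tables.
#' @param methods Character vector among `"none"`, `"enn"`,
#'   `"smote_enn"`, `"smote"`, `"vae"`.
#' @param ... Passed on to [plc_fit()] (iterations, seeds, ...).
#' @param seed Integer seed shared by all arms.
#' @param label Label column name.
#' @return A tibble with one row per method and split: `method`, `split`,
#'   `n_train_rows`, then the metric columns.
#' @export
compare_sampling <- function(train, test,
                             methods = c("none", "enn", "smote_enn",
                                         "smote", "vae"),
                             ..., seed = 1, label = "label") {
  methods <- match.arg(methods, several.ok = TRUE)
  train_parts <- table_parts(train, label = label)
  test_parts <- table_parts(test, label = label)
  purrr::map_dfr(methods, function(m) {
    fit <- plc_fit(train, augment = m, seed = seed, label = label, ...)
    pred_tr <- predict(fit, train)
    pred_te <- predict(fit, test)
    dplyr::bind_rows(
      dplyr::bind_cols(tibble(method = m, split = "train",
                              n_train_rows = nrow(fit$balanced)),
                       metric_row(train_parts$y, pred_tr$.pred,
                                  pred_tr$.prob)),
      dplyr::bind_cols(tibble(method = m, split = "test",
                              n_train_rows = nrow(fit$balanced)),
                       metric_row(test_parts$y, pred_te$.pred,
                                  pred_te$.prob)))
  })
}
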