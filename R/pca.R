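#' Fit a principal component analysis on a training split
#'
#' Centers the training descriptors and computes the eigenstructure of
#' their covariance matrix (unbiased `n - 1` denominator) via singular
#' value decomposition of the centered data matrix. Components are sorted
#' by descending eigenvalue, and each component's sign is fixed so that
#' its largest-magnitude loading is positive, making outputs reproducible.
#'
#' @param data Descriptor table (normalize first so that large-unit
#'   columns do not dominate the components).
#' @param label Label column name (ignored during fitting).
#' @return An object of class `"plc_pca"` with fields `mean`,
#'   `components` (orthonormal, columns = eigenvectors), `eigenvalues`
#'   (descending), `explained_variance_ratio` and `feature`.
#' @seealso [pca_scree()], [select_components()], [pca_transform()]
#' @export
fit_pca <- function(data, label = "label") {
  parts <- table_parts(data, label = label, require_label = FALSE)
  x <- parts$x
  n <- nrow(x); p <- ncol(x)
  if (n < 2L) {
    abort("PCA requires at least 2 rows.", class = "plc_error_empty_table")
  }
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu, "-")
  sv <- svd(xc, nu = 0)
  ev <- numeric(p)
  ev[seq_along(sv$d)] <- sv$d^2 / (n - 1)
  v <- sv$v
  if (ncol(v) < p) {
    # rank-deficient sample (n - 1 < p): complete to a full orthonormal basis
    comp <- qr.Q(qr(cbind(v, diag(p))))[, seq_len(p), drop = FALSE]
    comp[, seq_len(ncol(v))] <- v
    v <- comp
  }
  # deterministic sign: largest-|loading| entry of each component positive
  for (j in seq_len(p)) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) v[, j] <- -v[, j]
  }
  total <- sum(ev)
  structure(list(mean = mu,
                 components = v,
                 eigenvalues = ev,
                 explained_variance_ratio = if (total > 0) ev / total
                                            else rep(0, p),
                 feature = parts$features),
            class = "plc_pca")
}

#' @export
print.plc_pca <- function(x, ...) {
  k85 <- select_components(x)
  cat(sprintf("<plc_pca> %d features; %d components reach 85%% cumulative variance\n",
              length(x$feature), k85))
  invisible(x)
}

#' Scree table of a fitted PCA
#'
#' One row per component: eigenvalue, explained-variance ratio and the
#' non-decreasing cumulative ratio (final entry 1). This is the tabular
#' form of the scree plot used to pick the retained dimensionality.
#'
#' @param model A `"plc_pca"` object.
#' @return A tibble with columns `component`, `eigenvalue`,
#'   `variance_ratio`, `cumulative`.
#' @export
pca_scree <- function(model) {
  stopifnot(inherits(model, "plc_pca"))
  tibble(component = seq_along(model$eigenvalues),
         eigenvalue = model$eigenvalues,
         variance_ratio = model$explained_variance_ratio,
         cumulative = cumsum(model$explained_variance_ratio))
}

#' Choose the number of retained components
#'
#' By default returns the smallest `k` whose cumulative explained-variance
#' ratio reaches `cumulative_threshold` (85% by convention); `fixed_k`
#' overrides the rule outright (the reference pipeline fixes `k = 10`).
#'
#' @param model A `"plc_pca"` object.
#' @param cumulative_threshold Threshold in (0, 1\]; default 0.85.
#' @param fixed_k Optional integer override in `[1, n_features]`.
#' @return An integer `k`.
#' @export
select_components <- function(model, cumulative_threshold = 0.85,
                              fixed_k = NULL) {
  stopifnot(inherits(model, "plc_pca"))
  p <- length(model$eigenvalues)
  if (!is.null(fixed_k)) {
    fixed_k <- as.integer(fixed_k)
    if (fixed_k < 1L || fixed_k > p) {
      abort(sprintf("fixed_k must lie in [1, %d].", p),
            class = "plc_error_bad_k")
    }
    return(fixed_k)
  }
  cum <- cumsum(model$explained_variance_ratio)
  k <- which(cum >= cumulative_threshold - 1e-12)[1]
  if (is.na(k)) p else as.integer(k)
}

#' Project a descriptor table onto the top k components
#'
#' Computes `(X - mean) %*% components[, 1:k]`; labels are carried through
#' unchanged. Applied identically to training and test splits using the
#' training-fitted model.
#'
#' @param model A `"plc_pca"` object.
#' @param data Descriptor table with the same feature columns the model
#'   was fitted on.
#' @param k Number of components to keep (default: all).
#' @param label Label column name.
#' @return A tibble with columns `PC1 ... PCk` (+ the label column).
#' @export
pca_transform <- function(model, data, k = NULL, label = "label") {
  stopifnot(inherits(model, "plc_pca"))
  parts <- table_parts(data, label = label, require_label = FALSE)
  p <- length(model$feature)
  if (!identical(parts$features, model$feature)) {
    abort("Feature names of `data` do not match the fitted PCA.",
          class = "plc_error_feature_mismatch")
  }
  k <- as.integer(k %||% p)
  if (k < 1L || k > p) {
    abort(sprintf("k must lie in [1, %d].", p), class = "plc_error_bad_k")
  }
  scores <- sweep(parts$x, 2, model$mean, "-") %*%
    model$components[, seq_len(k), drop = FALSE]
  rebuild_table(scores, parts$y, paste0("PC", seq_len(k)), label = label)
}

#' Reconstruct descriptors from component scores
#'
#' Inverse of [pca_transform()]: `scores %*% t(components[, 1:k]) + mean`.
#' With `k = n_features` this recovers the original table to numerical
#' precision.
#'
#' @param model A `"plc_pca"` object.
#' @param scores Tibble or matrix of component scores (`PC1 ... PCk`).
#' @param label Label column name.
#' @return A tibble in the original descriptor space.
#' @export
pca_inverse <- function(model, scores, label = "label") {
  stopifnot(inherits(model, "plc_pca"))
  y <- NULL
  if (is.data.frame(scores)) {
    parts <- table_parts(scores, label = label, require_label = FALSE)
    y <- parts$y
    scores <- parts$x
  }
  k <- ncol(scores)
  x <- scores %*% t(model$components[, seq_len(k), drop = FALSE])
  x <- sweep(x, 2, model$mean, "+")
  rebuild_table(x, y, model$feature, label = label)
}
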