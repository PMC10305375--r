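# broom-style tidiers for the fitted objects.

#' Tidy a fitted PCA into its scree table
#'
#' @param x A `"plc_pca"`.
#' @param ... Unused.
#' @return The [pca_scree()] tibble.
#' @export
tidy.plc_pca <- function(x, ...) pca_scree(x)

#' One-row summary of a fitted PCA
#'
#' @param x A `"plc_pca"`.
#' @param ... Unused.
#' @return A tibble with `n_features`, `k_85` (components reaching 85%
#'   cumulative variance) and `total_variance`.
#' @export
glance.plc_pca <- function(x, ...) {
  tibble(n_features = length(x$feature),
         k_85 = select_components(x),
         total_variance = sum(x$eigenvalues))
}

#' Per-iteration loss history of a VAE fit
#'
#' @param x A `"plc_vae_fit"`.
#' @param ... Unused.
#' @return A tibble with `iteration`, `total`, `recon`, `kl`.
#' @export
tidy.plc_vae_fit <- function(x, ...) x$history

#' One-row summary of a VAE fit
#'
#' @param x A `"plc_vae_fit"`.
#' @param ... Unused.
#' @export
glance.plc_vae_fit <- function(x, ...) {
  n <- nrow(x$history)
  tibble(iterations = n,
         final_total = x$history$total[n],
         final_recon = x$history$recon[n],
         final_kl = x$history$kl[n])
}

#' Per-iteration history of a classifier fit
#'
#' @param x A `"plc_cnn_fit"`.
#' @param ... Unused.
#' @return A tibble with `iteration`, `loss`, `accuracy`.
#' @export
tidy.plc_cnn_fit <- function(x, ...) x$history

#' One-row summary of a classifier fit
#'
#' @param x A `"plc_cnn_fit"`.
#' @param ... Unused.
#' @export
glance.plc_cnn_fit <- function(x, ...) {
  n <- nrow(x$history)
  tibble(iterations = n,
         n_parameters = x$model$n_parameters,
         final_loss = x$history$loss[n],
         train_accuracy = x$history$accuracy[n])
}

#' Classifier history of a full pipeline fit
#'
#' @param x A `"plc_fit"`.
#' @param ... Unused.
#' @export
tidy.plc_fit <- function(x, ...) x$cnn$history

#' One-row summary of a full pipeline fit
#'
#' @param x A `"plc_fit"`.
#' @param ... Unused.
#' @return A tibble with the augmentation method, balanced training size,
#'   retained components, classifier parameter count and final training
#'   accuracy.
#' @export
glance.plc_fit <- function(x, ...) {
  tibble(augment = x$augment,
         n_balanced = nrow(x$balanced),
         k = x$k %||% NA_integer_,
         n_parameters = x$cnn$model$n_parameters,
         train_accuracy = x$cnn$history$accuracy[nrow(x$cnn$history)])
}
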