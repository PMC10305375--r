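# ggplot2 visual summaries of the fitted objects.

#' Scree plot of a fitted PCA
#'
#' Bars show the cumulative explained-variance ratio (with the 85%
#' selection threshold), the line the eigenvalues rescaled onto the same
#' axis.
#'
#' @param object A `"plc_pca"`.
#' @param threshold Cumulative-variance reference line (default 0.85).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.plc_pca <- function(object, threshold = 0.85, ...) {
  sc <- pca_scree(object)
  scale <- max(sc$eigenvalue)
  if (scale <= 0) scale <- 1
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$component)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$cumulative),
                      fill = "steelblue", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$eigenvalue / scale),
                       colour = "firebrick") +
    ggplot2::geom_point(ggplot2::aes(y = .data$eigenvalue / scale),
                        colour = "firebrick") +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::scale_y_continuous(
      "cumulative explained variance",
      sec.axis = ggplot2::sec_axis(~ . * scale, name = "eigenvalue")) +
    ggplot2::labs(x = "principal component") +
    ggplot2::theme_minimal()
}

#' Training curves of a VAE fit
#'
#' @param object A `"plc_vae_fit"`.
#' @param ... Unused.
#' @return A ggplot object (total / reconstruction / KL panels).
#' @export
autoplot.plc_vae_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, -"iteration",
                              names_to = "term", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$iteration, .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = "loss") +
    ggplot2::theme_minimal()
}

#' Training curves of a classifier fit
#'
#' @param object A `"plc_cnn_fit"`.
#' @param ... Unused.
#' @return A ggplot object (loss and training accuracy).
#' @export
autoplot.plc_cnn_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, -"iteration",
                              names_to = "term", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$iteration, .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = NULL) +
    ggplot2::theme_minimal()
}

#' Horizontal bar chart of descriptor importance
#'
#' @param object A `"plc_importance"` report.
#' @param k Show the top `k` descriptors (default 20, clamped).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.plc_importance <- function(object, k = 20, ...) {
  k <- min(k, nrow(object))
  top <- top_descriptors(object, k)
  top$feature <- factor(top$feature, levels = rev(top$feature))
  mapping <- if ("group" %in% names(top)) {
    ggplot2::aes(.data$score, .data$feature, fill = .data$group)
  } else {
    ggplot2::aes(.data$score, .data$feature)
  }
  ggplot2::ggplot(top, mapping) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "relative importance", y = NULL) +
    ggplot2::theme_minimal()
}

#' Latent-space scatter of original and generated formulations
#'
#' Encodes both tables with the fitted VAE and plots the posterior means,
#' coloured by outcome and shaped by origin — the visual check that
#' generated minority rows land inside the minority cluster.
#'
#' @param model A `"plc_vae_fit"` (or `"plc_vae"`).
#' @param original Normalized descriptor table of original rows.
#' @param generated Optional table of generated rows.
#' @param label Label column name.
#' @return A ggplot object.
#' @export
plot_latent <- function(model, original, generated = NULL,
                        label = "label") {
  coords <- latent_coordinates(model, original, label = label,
                               origin = "original")
  if (!is.null(generated)) {
    coords <- dplyr::bind_rows(
      coords,
      latent_coordinates(model, generated, label = label,
                         origin = "generated"))
  }
  coords$label <- factor(coords$label, levels = c(1, 0),
                         labels = c("success", "failure"))
  ggplot2::ggplot(coords,
                  ggplot2::aes(.data$z1, .data$z2, colour = .data$label,
                               shape = .data$origin)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "z1", y = "z2") +
    ggplot2::theme_minimal()
}
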