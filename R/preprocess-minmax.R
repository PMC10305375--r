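#' Fit min-max normalization parameters on a training split
#'
#' Records the column-wise minimum and maximum of the training descriptors.
#' Scaling every variable to a common \[0, 1\] range matters here because
#' raw descriptor units differ by orders of magnitude (molecular weight in
#' the hundreds vs. logP near zero), which would otherwise dominate both
#' gradient-based training and principal-component selection.
#'
#' @param data Training descriptor table.
#' @param label Name of the label column (default `"label"`); set to a
#'   column absent from `data` only if the table truly has no label.
#' @return An object of class `"plc_minmax"` with fields `feature`, `min`,
#'   `max`.
#' @seealso [apply_minmax()], [invert_minmax()]
#' @export
fit_minmax <- function(data, label = "label") {
  parts <- table_parts(data, label = label, require_label = FALSE)
  if (nrow(parts$x) < 1L) {
    abort("Cannot fit normalization on an empty table.",
          class = "plc_error_empty_table")
  }
  structure(list(feature = parts$features,
                 min = apply(parts$x, 2, min),
                 max = apply(parts$x, 2, max)),
            class = "plc_minmax")
}

#' @export
print.plc_minmax <- function(x, ...) {
  cat(sprintf("<plc_minmax> %d features\n", length(x$feature)))
  invisible(x)
}

#' Apply (or invert) a fitted min-max transform
#'
#' `apply_minmax()` maps every descriptor to
#' `(x - min) / (max - min)` using the *training* extrema, so training
#' columns land in \[0, 1\] while test values may legitimately fall outside
#' that interval. Zero-range (constant) columns map to 0 — they carry no
#' information and stay inert rather than producing NaN. Labels pass
#' through untouched. `invert_minmax()` undoes the map (constant columns
#' are restored to their training value).
#'
#' @param params A `"plc_minmax"` object from [fit_minmax()].
#' @param data Descriptor table whose feature columns match `params`
#'   (same names, same order).
#' @param label Name of the label column, if present.
#' @return A tibble of the same shape as `data`.
#' @examples
#' tbl <- tibble::tibble(mw = c(200, 650, 1100), label = c(1, 0, 1))
#' apply_minmax(fit_minmax(tbl), tbl)
#' @export
apply_minmax <- function(params, data, label = "label") {
  parts <- minmax_parts(params, data, label)
  rng <- params$max - params$min
  x <- sweep(parts$x, 2, params$min, "-")
  x <- sweep(x, 2, ifelse(rng > 0, rng, 1), "/")
  x[, rng == 0] <- 0
  rebuild_table(x, parts$y, parts$features, label = label)
}

#' @rdname apply_minmax
#' @export
invert_minmax <- function(params, data, label = "label") {
  parts <- minmax_parts(params, data, label)
  rng <- params$max - params$min
  x <- sweep(parts$x, 2, rng, "*")
  x <- sweep(x, 2, params$min, "+")
  if (any(rng == 0)) {
    x[, rng == 0] <- rep(params$min[rng == 0], each = nrow(x))
  }
  rebuild_table(x, parts$y, parts$features, label = label)
}

minmax_parts <- function(params, data, label) {
  stopifnot(inherits(params, "plc_minmax"))
  parts <- table_parts(data, label = label, require_label = FALSE)
  if (!identical(parts$features, params$feature)) {
    abort("Feature names of `data` do not match the fitted parameters.",
          class = "plc_error_feature_mismatch")
  }
  parts
}

#' Save / load min-max parameters
#'
#' Serializes the fitted extrema to YAML so that exactly the same transform
#' can be re-applied at test time.
#'
#' @param params A `"plc_minmax"` object.
#' @param path YAML file path.
#' @return `write_minmax()` returns `path` invisibly; `read_minmax()`
#'   returns a `"plc_minmax"` object.
#' @export
write_minmax <- function(params, path) {
  stopifnot(inherits(params, "plc_minmax"))
  yaml::write_yaml(list(feature = params$feature,
                        min = as.numeric(params$min),
                        max = as.numeric(params$max)), path)
  invisible(path)
}

#' @rdname write_minmax
#' @export
read_minmax <- function(path) {
  raw <- yaml::read_yaml(path)
  structure(list(feature = as.character(raw$feature),
                 min = stats::setNames(as.numeric(raw$min), raw$feature),
                 max = stats::setNames(as.numeric(raw$max), raw$feature)),
            class = "plc_minmax")
}
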