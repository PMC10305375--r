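# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed without disturbing the caller's RNG
# state. All user-facing stochastic operations funnel through this so that
# identical seeds give bit-identical results.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# Derive a child seed from a pipeline seed; keeps results < 2^31.
child_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) * 101L + as.integer(offset)) %% 2147483647L
}

sigmoid <- function(a) 1 / (1 + exp(-a))

# log(1 + exp(a)) without overflow
softplus <- function(a) {
  out <- pmax(a, 0)
  out + log1p(exp(-abs(a)))
}

relu <- function(a) {
  a[a < 0] <- 0
  a
}

# Validate a descriptor data frame and split it into a numeric feature
# matrix and an integer 0/1 label vector. Every public function that takes
# tabular input goes through here.
table_parts <- function(data, label = "label", require_label = TRUE,
                        arg = "data") {
  if (!is.data.frame(data)) {
    abort(sprintf("`%s` must be a data frame.", arg),
          class = "plc_error_not_data_frame")
  }
  has_label <- label %in% names(data)
  if (require_label && !has_label) {
    abort(sprintf("Label column '%s' not found in `%s`.", label, arg),
          class = "plc_error_label_missing")
  }
  feat_cols <- setdiff(names(data), if (has_label) label else character())
  if (anyDuplicated(feat_cols)) {
    abort("Feature names must be unique.", class = "plc_error_duplicate_names")
  }
  x <- data[feat_cols]
  non_num <- !vapply(x, is.numeric, logical(1))
  if (any(non_num)) {
    abort(sprintf("Non-numeric descriptor column(s): %s.",
                  paste(feat_cols[non_num], collapse = ", ")),
          class = "plc_error_non_numeric")
  }
  x <- as.matrix(x)
  dimnames(x) <- NULL
  if (nrow(data) > 0L && anyNA(x)) {
    abort("Descriptor table contains missing values.",
          class = "plc_error_missing_values")
  }
  y <- NULL
  if (has_label) {
    y <- coerce_binary_label(data[[label]])
    if (anyNA(y)) {
      abort("Label column contains missing values.",
            class = "plc_error_missing_values")
    }
  }
  list(x = x, y = y, features = feat_cols, label = label)
}

# Map a two-level label vector onto integer {0, 1}. Numeric 0/1 passes
# through; "success"/"failure" map to 1/0; anything else with more than two
# levels errors.
coerce_binary_label <- function(values) {
  lev <- unique(values[!is.na(values)])
  if (length(lev) > 2L) {
    abort(sprintf("Label column has %d distinct values; exactly 2 (or fewer) are allowed.",
                  length(lev)),
          class = "plc_error_label_levels")
  }
  if (is.numeric(values)) {
    if (!all(lev %in% c(0, 1))) {
      abort("Numeric labels must be coded 0/1.",
            class = "plc_error_label_levels")
    }
    return(as.integer(values))
  }
  chr <- tolower(as.character(values))
  known <- c(success = 1L, failure = 0L, yes = 1L, no = 0L,
             "1" = 1L, "0" = 0L, "true" = 1L, "false" = 0L)
  if (all(unique(chr) %in% names(known))) {
    return(unname(known[chr]))
  }
  abort(sprintf("Cannot map label values (%s) onto {0, 1}; use 0/1 or success/failure coding.",
                paste(lev, collapse = ", ")),
        class = "plc_error_label_levels")
}

# Rebuild a tibble from a feature matrix + labels, preserving column order.
rebuild_table <- function(x, y, features, label = "label") {
  out <- as_tibble(as.data.frame(x))
  names(out) <- features
  if (!is.null(y)) out[[label]] <- as.integer(y)
  out
}
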