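#' Read a descriptor table from CSV
#'
#' A descriptor table is the tabular currency of the whole pipeline: one row
#' per formulation experiment, numeric molecular-descriptor columns (drug,
#' phospholipid, solvent and experimental-condition properties), and one
#' binary outcome column — 1 when the drug–phospholipid complex formed
#' (complexation rate at or above 80%), 0 otherwise.
#'
#' The label column may be coded `0`/`1` or `"success"`/`"failure"`
#' (`"success"` maps to 1, the positive class for sensitivity). An optional
#' YAML sidecar can assign each descriptor to a group
#' (`api`, `lipid`, `solvent` or `condition`); the mapping is attached as the
#' `"groups"` attribute and carried into importance reports.
#'
#' @param path Path to a CSV file with a header row.
#' @param label Name of the label column. Default `"label"`.
#' @param groups Optional path to a YAML file mapping descriptor names to
#'   groups, or a named character vector doing the same.
#' @return A tibble of numeric descriptor columns plus an integer `label`
#'   column, validated (no missing values, strictly binary label).
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("mw,logp,label", "230,1.2,success", "410,3.4,failure"), tf)
#' read_descriptor_table(tf)
#' @export
read_descriptor_table <- function(path, label = "label", groups = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "plc_error_missing_file")
  }
  # read as text and convert with base strtod: the fast type-guessing
  # parser is not correctly rounded in the last ulp
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  for (nm in setdiff(names(raw), label)) {
    chr <- raw[[nm]]
    num <- suppressWarnings(as.numeric(chr))
    bad <- !is.na(chr) & chr != "" & is.na(num)
    if (any(bad)) {
      abort(sprintf("Non-numeric descriptor cell(s) in column '%s'.", nm),
            class = "plc_error_non_numeric")
    }
    raw[[nm]] <- num
  }
  if (label %in% names(raw)) {
    lab <- raw[[label]]
    numlab <- suppressWarnings(as.numeric(lab))
    if (!anyNA(numlab)) raw[[label]] <- numlab
  }
  parts <- table_parts(raw, label = label, arg = "path")
  out <- rebuild_table(parts$x, parts$y, parts$features, label = label)
  if (!is.null(groups)) {
    attr(out, "groups") <- read_feature_groups(groups, parts$features)
  }
  out
}

read_feature_groups <- function(groups, features) {
  if (is.character(groups) && length(groups) == 1L && file.exists(groups)) {
    groups <- unlist(yaml::read_yaml(groups))
  }
  groups <- unlist(groups)
  bad <- setdiff(unique(groups), c("api", "lipid", "solvent", "condition"))
  if (length(bad) > 0L) {
    abort(sprintf("Unknown descriptor group(s): %s.", paste(bad, collapse = ", ")),
          class = "plc_error_bad_group")
  }
  missing <- setdiff(features, names(groups))
  if (length(missing) > 0L) {
    abort(sprintf("No group assigned for descriptor(s): %s.",
                  paste(missing, collapse = ", ")),
          class = "plc_error_bad_group")
  }
  groups[features]
}

#' Write a descriptor table to CSV
#'
#' Writes with shortest-round-trip formatting so that
#' `read_descriptor_table()` recovers the features to full double precision
#' (read–write is the identity on valid tables).
#'
#' @param data A descriptor table (data frame with numeric descriptors and a
#'   binary label column).
#' @param path Output file path; the directory must exist.
#' @param label Name of the label column. Default `"label"`.
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(data, path, label = "label") {
  parts <- table_parts(data, label = label)
  if (!dir.exists(dirname(path))) {
    abort(sprintf("Directory does not exist: %s", dirname(path)),
          class = "plc_error_unwritable_path")
  }
  out <- rebuild_table(parts$x, parts$y, parts$features, label = label)
  # %.17g guarantees exact double round-trip (shortest formatters are not
  # always bit-faithful)
  for (nm in parts$features) out[[nm]] <- sprintf("%.17g", out[[nm]])
  if (nrow(out) == 0L) for (nm in parts$features) out[[nm]] <- character()
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Count successes and failures in a descriptor table
#'
#' @inheritParams write_descriptor_table
#' @return A one-row tibble with `n_success`, `n_failure` and `n_total`.
#'   Counts always sum to the number of rows.
#' @examples
#' tbl <- tibble::tibble(x = 1:4, label = c(1, 1, 0, 1))
#' class_counts(tbl)
#' @export
class_counts <- function(data, label = "label") {
  parts <- table_parts(data, label = label)
  n1 <- sum(parts$y == 1L)
  tibble(n_success = n1,
         n_failure = length(parts$y) - n1,
         n_total = length(parts$y))
}
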