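#' Write a feature table as CSV with a sidecar missingness mask
#'
#' Feature tables travel as plain CSV with the mask convention: each
#' feature column `f` is accompanied by a logical column `f__missing`.
#' Masked entries are written as their imputed/placeholder value (or
#' empty when `NA`), and the sidecar column records which entries were
#' missing before imputation.
#'
#' @param table Feature tibble.
#' @param path Output CSV path.
#' @param mask Optional logical matrix (wells x features, TRUE = missing);
#'   default: the `NA` pattern of the feature columns.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, mask = NULL) {
  fc <- feature_cols(table)
  if (is.null(mask)) {
    mask <- is.na(as.matrix(table[, fc]))
  }
  stopifnot(nrow(mask) == nrow(table), ncol(mask) == length(fc))
  out <- table[, setdiff(names(table), fc)]
  for (j in seq_along(fc)) {
    out[[fc[j]]] <- table[[fc[j]]]
    out[[paste0(fc[j], "__missing")]] <- as.logical(mask[, j])
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a feature table written with the sidecar mask convention
#'
#' @param path CSV path written by [write_feature_table()].
#' @return List with `table` (feature tibble, masked entries set `NA`) and
#'   `mask` (logical matrix).
#' @export
read_feature_table <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  miss_cols <- grep("__missing$", names(raw), value = TRUE)
  fc <- sub("__missing$", "", miss_cols)
  stopifnot(all(fc %in% names(raw)))
  mask <- as.matrix(raw[, miss_cols])
  colnames(mask) <- fc
  tab <- raw[, setdiff(names(raw), miss_cols)]
  for (j in seq_along(fc)) {
    tab[[fc[j]]][mask[, j]] <- NA
  }
  attr(tab, "feature_cols") <- fc
  list(table = tab, mask = unname(mask))
}
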