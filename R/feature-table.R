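# Aligned feature matrix CSV I/O. A feature matrix is a data frame with
# columns mz, rt_s, then one area column per sample; absent (undetected)
# cells are NA in memory and empty fields on disk, never zero.

#' Write an aligned feature matrix to CSV
#'
#' @param features Feature matrix data frame (`mz`, `rt_s`, one column per
#'   sample). Missing cells are written as empty fields.
#' @param path Output CSV path (UTF-8, comma-delimited, '.' decimal).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  stopifnot(is.data.frame(features),
            all(c("mz", "rt_s") %in% names(features)))
  utils::write.csv(features, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read an aligned feature matrix from CSV
#'
#' Inverse of [write_feature_table()]; empty fields come back as `NA`
#' (absent), not zero.
#'
#' @param path CSV path.
#' @return Feature matrix data frame.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  out <- utils::read.csv(path, check.names = FALSE)
  for (j in seq_along(out)) out[[j]] <- as.numeric(out[[j]])
  out
}
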