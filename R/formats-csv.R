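#' Write a count table to CSV
#'
#' One row per mature/family id, one column per library, integer cells —
#' the "DESeq2-ready" layout shared by all count outputs.
#'
#' @param table data.frame whose first column is `id` and remaining
#'   columns are per-library counts.
#' @param path output path.
#' @export
write_counts_csv <- function(table, path) {
  stopifnot(names(table)[1] == "id")
  write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a count table written by [write_counts_csv()]
#'
#' @param path CSV path.
#' @return data.frame with an `id` column and per-library count columns.
#' @export
read_counts_csv <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(out)[1] <- "id"
  out
}

#' Assemble per-library named count vectors into one table
#'
#' @param libs named list of named numeric vectors (one per library).
#' @return data.frame with `id` plus one column per library, missing ids
#'   filled with 0, rows sorted by id.
#' @export
build_count_table <- function(libs) {
  ids <- sort(unique(unlist(lapply(libs, names))))
  out <- data.frame(id = ids, stringsAsFactors = FALSE)
  for (lib in names(libs)) {
    v <- libs[[lib]]
    out[[lib]] <- ifelse(ids %in% names(v), unname(v[ids]), 0)
  }
  out
}
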