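#' Read and write count matrices as TSV
#'
#' Counts travel as a plain TSV with a `mirna_id` column followed by one
#' column per sample. On reading, library sizes are taken as the column
#' totals (the "total copy number" convention the CPM normalization
#' expects).
#'
#' @param counts A [mir_counts()] object.
#' @param path TSV path.
#' @param group Optional per-sample group labels applied on reading.
#' @return `read_counts_tsv()` returns a [mir_counts()]; writers return the
#'   path invisibly.
#' @export
write_counts_tsv <- function(counts, path) {
  stopifnot(inherits(counts, "mir_counts"))
  df <- data.frame(mirna_id = rownames(counts$counts), counts$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  tsv_write(df, path)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path, group = NULL) {
  df <- tsv_read(path)
  if (names(df)[1] != "mirna_id")
    abort_arg("counts TSV must start with a mirna_id column")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$mirna_id
  mir_counts(m, group = group)
}

#' Write a differential-expression or gradient table as TSV
#'
#' @param table A data frame (e.g. from [de_table()] or [gradient_table()]).
#' @param path TSV path.
#' @return The path, invisibly.
#' @export
write_table_tsv <- function(table, path) {
  tsv_write(table, path)
  invisible(path)
}
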