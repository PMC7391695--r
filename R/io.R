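#' Read and write abundance tables as TSV
#'
#' Tables are tab-separated with a `#taxon_id` header for the first column,
#' one column of integer counts per sample, and an optional trailing
#' `taxonomy` column of lineage strings.
#'
#' @param path file path.
#' @return `read_abundance_table()` returns an `abundance_table` flagged as
#'   counts; `write_abundance_table()` invisibly returns `path`.
#' @export
read_abundance_table <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "",
                          check.names = FALSE, colClasses = "character")
  names(df) <- header
  if (anyDuplicated(header))
    stopf("duplicated column header: %s",
          paste(unique(header[duplicated(header)]), collapse = ", "))
  has_tax <- tolower(header[length(header)]) == "taxonomy"
  sample_cols <- seq.int(2L, length(header) - has_tax)
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stopf("duplicated taxon id: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- matrix(NA_real_, nrow(df), length(sample_cols),
              dimnames = list(ids, header[sample_cols]))
  for (j in seq_along(sample_cols)) {
    v <- suppressWarnings(as.numeric(df[[sample_cols[j]]]))
    bad <- which(is.na(v) | v < 0)
    if (length(bad))
      stopf("non-numeric or negative count at row %d, column '%s'",
            bad[1L], header[sample_cols[j]])
    m[, j] <- v
  }
  lin <- if (has_tax) df[[length(header)]] else rep("", nrow(df))
  abundance_table(m, stats::setNames(lin, ids), "counts")
}

#' @rdname read_abundance_table
#' @param x an `abundance_table`.
#' @export
write_abundance_table <- function(x, path) {
  stopifnot(inherits(x, "abundance_table"))
  df <- data.frame(`#taxon_id` = taxon_ids(x), x$counts,
                   taxonomy = format_taxonomy(x$lineages),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write sample metadata
#'
#' Metadata is a TSV with required columns `sample_id`, `group`
#' (`case`/`control`) and `severity` (`mild`, `moderate_severe`,
#' `not_applicable`); any further columns are carried along as covariates.
#' Severity is `not_applicable` exactly for controls.
#'
#' @param path file path.
#' @return A data.frame of class `sample_metadata`.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  sample_metadata(df)
}

#' @rdname read_sample_metadata
#' @param df a data.frame with the required columns (validates and classes it).
#' @export
sample_metadata <- function(df) {
  need <- c("sample_id", "group", "severity")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stopf("metadata lacks column(s): %s", paste(missing, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stopf("duplicated sample_id in metadata")
  if (!all(df$group %in% c("case", "control")))
    stopf("group must be 'case' or 'control'")
  if (!all(df$severity %in% c("mild", "moderate_severe", "not_applicable")))
    stopf("invalid severity value")
  if (!all((df$severity == "not_applicable") == (df$group == "control")))
    stopf("severity must be not_applicable exactly for controls")
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' @rdname read_sample_metadata
#' @param md a `sample_metadata` data.frame.
#' @export
write_sample_metadata <- function(md, path) {
  utils::write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
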