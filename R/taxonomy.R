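#' Greengenes-style taxonomy lineages
#'
#' Parse semicolon-separated lineage strings into rank-labelled vectors.
#' Both the Greengenes prefixed dialect (`k__Bacteria; p__Firmicutes; ...`)
#' and bare positional lineages (`Bacteria;Firmicutes;...`) are accepted;
#' ranks absent from the string are explicit empty strings, never dropped.
#'
#' @param x character vector of lineage strings.
#' @return For `parse_taxonomy()`, a data.frame with one row per input and
#'   columns `kingdom`, `phylum`, `class`, `order`, `family`, `genus`,
#'   `species` plus `raw` (the original string). For `format_taxonomy()`, a
#'   character vector in the prefixed Greengenes dialect.
#' @examples
#' parse_taxonomy("k__Bacteria; p__Firmicutes; c__Clostridia")$phylum
#' @export
parse_taxonomy <- function(x) {
  stopifnot(is.character(x))
  out <- do.call(rbind, lapply(x, parse_one_lineage))
  out$raw <- x
  rownames(out) <- NULL
  out
}

tax_ranks <- c("kingdom", "phylum", "class", "order", "family", "genus",
               "species")
tax_prefixes <- c("k__", "p__", "c__", "o__", "f__", "g__", "s__")

parse_one_lineage <- function(s) {
  parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  vals <- stats::setNames(rep("", 7L), tax_ranks)
  prefixed <- grepl("^[a-zA-Z]__", parts)
  if (any(prefixed)) {
    if (!all(prefixed | parts == ""))
      stopf("lineage mixes prefixed and bare fields: %s", s)
    parts <- parts[parts != ""]
    idx <- match(substr(parts, 1L, 3L), tax_prefixes)
    if (anyNA(idx)) stopf("unknown rank prefix in lineage: %s", s)
    if (is.unsorted(idx, strictly = TRUE))
      stopf("rank prefixes out of canonical order in lineage: %s", s)
    vals[idx] <- substring(parts, 4L)
  } else {
    parts <- parts[!(parts == "" & seq_along(parts) > 1L)]
    n <- min(length(parts), 7L)
    vals[seq_len(n)] <- parts[seq_len(n)]
  }
  as.data.frame(as.list(vals), stringsAsFactors = FALSE)
}

#' @rdname parse_taxonomy
#' @param lineages a data.frame as returned by `parse_taxonomy()` (the `raw`
#'   column is ignored).
#' @export
format_taxonomy <- function(lineages) {
  stopifnot(is.data.frame(lineages), all(tax_ranks %in% names(lineages)))
  apply(lineages[tax_ranks], 1L, function(v) {
    keep <- which(v != "")
    n <- if (length(keep)) max(keep) else 1L
    paste0(tax_prefixes[seq_len(n)], v[seq_len(n)], collapse = "; ")
  })
}
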