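#' Taxon-by-sample abundance tables
#'
#' The universal currency of the pipeline: a non-negative taxon x sample
#' matrix (reads or proportions, flagged which) plus a taxonomy lineage per
#' taxon. Taxa are rows, samples are columns.
#'
#' @param counts numeric matrix, taxa as rows with unique rownames, samples
#'   as columns with unique colnames; all values must be >= 0.
#' @param lineages character vector of lineage strings, one per taxon (named
#'   by taxon id, or in row order), or a data.frame from [parse_taxonomy()].
#' @param type `"counts"` or `"proportions"`.
#' @return An object of class `abundance_table`: a list with elements
#'   `counts`, `lineages` (parsed data.frame with rownames = taxon ids) and
#'   `type`.
#' @examples
#' m <- matrix(c(3, 1, 4, 1), 2, 2,
#'             dimnames = list(c("t1", "t2"), c("s1", "s2")))
#' abundance_table(m, c("k__Bacteria; g__Blautia", "k__Bacteria"))
#' @export
abundance_table <- function(counts, lineages, type = c("counts", "proportions")) {
  type <- match.arg(type)
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("counts must carry taxon rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stopf("duplicate taxon id: %s",
          paste(unique(rownames(counts)[duplicated(rownames(counts))]),
                collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stopf("duplicate sample id: %s",
          paste(unique(colnames(counts)[duplicated(colnames(counts))]),
                collapse = ", "))
  if (anyNA(counts) || any(counts < 0))
    stopf("counts must be non-negative and non-missing")
  if (is.character(lineages)) {
    if (!is.null(names(lineages))) {
      missing <- setdiff(rownames(counts), names(lineages))
      if (length(missing))
        stopf("no lineage for taxon: %s", paste(missing, collapse = ", "))
      lineages <- lineages[rownames(counts)]
    } else if (length(lineages) != nrow(counts)) {
      stopf("need one lineage per taxon")
    }
    lineages <- parse_taxonomy(unname(lineages))
  }
  stopifnot(is.data.frame(lineages), nrow(lineages) == nrow(counts))
  rownames(lineages) <- rownames(counts)
  if (type == "proportions") {
    tot <- colSums(counts)
    bad <- which(abs(tot - 1) > 1e-9)
    if (length(bad))
      stopf("proportion columns must sum to 1: %s",
            paste(colnames(counts)[bad], collapse = ", "))
  }
  structure(list(counts = counts, lineages = lineages, type = type),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d taxa x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts), x$type))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$counts)

taxon_ids <- function(x) rownames(x$counts)
sample_ids <- function(x) colnames(x$counts)

#' Remove low-confidence taxa
#'
#' Drops every taxon whose total read count across all samples is strictly
#' below `min_fraction` of the grand total (default 0.1%, the conventional
#' low-confidence OTU filter for open-reference 16S tables). A taxon sitting
#' exactly at the threshold is retained.
#'
#' @param x an `abundance_table` of counts.
#' @param min_fraction minimum total-read fraction for a taxon to be kept.
#' @return The filtered table; dropped taxon ids are attached as
#'   `attr(, "dropped")`.
#' @export
filter_low_confidence <- function(x, min_fraction = 0.001) {
  stopifnot(inherits(x, "abundance_table"))
  if (x$type != "counts") stopf("filter_low_confidence expects a counts table")
  if (nrow(x$counts) == 0L || sum(x$counts) == 0) stopf("empty table")
  stopifnot(is.numeric(min_fraction), min_fraction >= 0)
  tot <- rowSums(x$counts)
  keep <- tot >= min_fraction * sum(tot)
  if (!any(keep)) stopf("all taxa fall below the %.4g threshold", min_fraction)
  out <- abundance_table(x$counts[keep, , drop = FALSE],
                         x$lineages[keep, , drop = FALSE], x$type)
  attr(out, "dropped") <- taxon_ids(x)[!keep]
  out
}

#' Collapse a table to a taxonomic rank
#'
#' Sums counts over taxa sharing the named rank. Taxa with an empty value at
#' that rank are pooled under `unclassified_<parent rank>_<parent name>` so
#' that genus sets used by downstream indices stay unambiguous. Per-sample
#' totals are conserved exactly.
#'
#' @param x an `abundance_table`.
#' @param rank one of `"phylum"`, `"class"`, `"order"`, `"family"`, `"genus"`.
#' @return An `abundance_table` whose taxa are the distinct rank values.
#' @export
collapse_to_rank <- function(x, rank = c("genus", "family", "order", "class",
                                         "phylum")) {
  stopifnot(inherits(x, "abundance_table"))
  rank <- match.arg(rank)
  ri <- match(rank, tax_ranks)
  vals <- x$lineages[[rank]]
  lab <- vals
  for (i in which(vals == "")) {
    parent <- which(unlist(x$lineages[i, tax_ranks[seq_len(ri - 1L)]]) != "")
    if (length(parent)) {
      p <- max(parent)
      lab[i] <- paste0("unclassified_", tax_ranks[p], "_",
                       x$lineages[i, tax_ranks[p]])
    } else {
      lab[i] <- "unclassified_root_"
    }
  }
  groups <- factor(lab, levels = unique(lab))
  m <- rowsum(x$counts, groups, reorder = FALSE)
  # representative lineage truncated at the collapse rank
  rep_idx <- match(levels(groups), lab)
  lin <- x$lineages[rep_idx, tax_ranks, drop = FALSE]
  lin[, tax_ranks[seq_len(7L)[-seq_len(ri)]]] <- ""
  unc <- vals[rep_idx] == ""
  lin[unc, rank] <- rownames(m)[unc]
  lin$raw <- format_taxonomy(lin)
  rownames(m) <- rownames(lin) <- levels(groups)
  abundance_table(m, lin, x$type)
}

#' Convert counts to relative abundances
#'
#' Divides each sample column by its total and flags the table as
#' proportions. Idempotent on proportion tables.
#'
#' @param x an `abundance_table`.
#' @return An `abundance_table` flagged `proportions`.
#' @export
to_relative <- function(x) {
  stopifnot(inherits(x, "abundance_table"))
  tot <- colSums(x$counts)
  if (any(tot == 0))
    stopf("sample has zero total: %s",
          paste(sample_ids(x)[tot == 0], collapse = ", "))
  abundance_table(sweep(x$counts, 2L, tot, "/"), x$lineages, "proportions")
}
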