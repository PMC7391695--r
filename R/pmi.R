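#' Define a Psoriasis-Microbiome Index from differential features
#'
#' The PMI numerator is the set of case-enriched genera, the denominator the
#' set of control-enriched genera. The per-sample score (see
#' [compute_pmi()]) is the log (base 10 by default) of the summed relative
#' abundance of the numerator over the denominator, making high scores
#' characteristic of the dysbiotic (case) state.
#'
#' @param features a `differential_features` data.frame (from [lefse()]) or
#'   any data.frame with `genus` and `direction` columns; both directions
#'   must be present and no genus may appear in both.
#' @param log_base logarithm base.
#' @param pseudocount `"half_min_nonzero"` (half the smallest nonzero genus
#'   proportion of the scored table, applied only when a sum is zero) or a
#'   fixed positive number.
#' @return list of class `index_definition` with `increased_genera`,
#'   `decreased_genera`, `log_base`, `pseudocount`.
#' @export
define_index <- function(features, log_base = 10,
                         pseudocount = "half_min_nonzero") {
  stopifnot(is.data.frame(features),
            all(c("genus", "direction") %in% names(features)))
  up <- sort(unique(features$genus[features$direction == "case_enriched"]))
  down <- sort(unique(features$genus[features$direction == "control_enriched"]))
  if (!length(up) || !length(down))
    stopf("need at least one feature in each direction")
  both <- intersect(up, down)
  if (length(both))
    stopf("genus in both directions: %s", paste(both, collapse = ", "))
  if (is.character(pseudocount))
    pseudocount <- match.arg(pseudocount, "half_min_nonzero")
  else stopifnot(is.numeric(pseudocount), pseudocount > 0)
  structure(list(increased_genera = up, decreased_genera = down,
                 log_base = log_base, pseudocount = pseudocount),
            class = "index_definition")
}

#' @export
print.index_definition <- function(x, ...) {
  cat("PMI index definition\n",
      " increased (numerator):  ", paste(x$increased_genera, collapse = ", "),
      "\n  decreased (denominator):", paste(x$decreased_genera, collapse = ", "),
      "\n  log base:", x$log_base, " pseudocount:", format(x$pseudocount), "\n")
  invisible(x)
}

#' Serialize / deserialize an index definition as JSON
#' @param idx an `index_definition`.
#' @param path file path.
#' @export
write_index <- function(idx, path) {
  stopifnot(inherits(idx, "index_definition"))
  jsonlite::write_json(list(increased = idx$increased_genera,
                            decreased = idx$decreased_genera,
                            log_base = jsonlite::unbox(idx$log_base),
                            pseudocount = jsonlite::unbox(idx$pseudocount)),
                       path, digits = NA)
  invisible(path)
}

#' @rdname write_index
#' @export
read_index <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  define_index(data.frame(
    genus = c(j$increased, j$decreased),
    direction = rep(c("case_enriched", "control_enriched"),
                    c(length(j$increased), length(j$decreased)))),
    log_base = j$log_base, pseudocount = j$pseudocount)
}

#' Compute per-sample PMI scores
#'
#' `score = log_b((sum of increased genera + pi) / (sum of decreased genera
#' + pi))` on relative abundances, where the pseudocount `pi` is applied
#' only when either sum is zero. Index genera absent from the table
#' contribute zero and trigger a warning.
#'
#' @param x an `abundance_table` of genus-level proportions.
#' @param idx an `index_definition`.
#' @return named numeric vector of scores, one per sample.
#' @export
compute_pmi <- function(x, idx) {
  stopifnot(inherits(x, "abundance_table"), inherits(idx, "index_definition"))
  if (x$type != "proportions")
    stopf("compute_pmi expects a relative-abundance table; see to_relative()")
  genera <- x$lineages$genus
  up <- match_index_genera(idx$increased_genera, genera, taxon_ids(x))
  down <- match_index_genera(idx$decreased_genera, genera, taxon_ids(x))
  if (!length(up$rows) && !length(down$rows))
    stopf("none of the index genera are present in the table")
  miss <- c(up$missing, down$missing)
  if (length(miss))
    warning("index genera absent from table (contribute 0): ",
            paste(miss, collapse = ", "), call. = FALSE)
  num <- colSums(x$counts[up$rows, , drop = FALSE])
  den <- colSums(x$counts[down$rows, , drop = FALSE])
  eps <- if (identical(idx$pseudocount, "half_min_nonzero")) {
    nz <- x$counts[x$counts > 0]
    if (!length(nz)) stopf("table has no nonzero abundance")
    min(nz) / 2
  } else idx$pseudocount
  pad <- (num == 0) | (den == 0)
  log((num + eps * pad) / (den + eps * pad), base = idx$log_base)
}

match_index_genera <- function(wanted, genera, ids) {
  hit <- genera %in% wanted | ids %in% wanted
  found <- unique(c(genera[hit], ids[hit]))
  list(rows = which(hit), missing = setdiff(wanted, found))
}

#' ROC curve for a case/control score
#'
#' Thresholds are the midpoints between consecutive distinct sorted scores
#' plus `-Inf`/`+Inf` sentinels; a sample is called a case when its score is
#' at or above the threshold. The AUC is the trapezoidal area, equal to the
#' probability that a random case outscores a random control (ties counted
#' half).
#'
#' @param scores numeric score per sample.
#' @param labels `"case"`/`"control"` per sample (both must occur).
#' @return list of class `roc_curve` with `thresholds` (descending),
#'   `sensitivity`, `specificity`, `auc`.
#' @export
roc_curve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.character(labels)
  if (!all(labels %in% c("case", "control")))
    stopf("labels must be 'case' or 'control'")
  n_case <- sum(labels == "case")
  n_ctrl <- sum(labels == "control")
  if (n_case == 0 || n_ctrl == 0) stopf("both classes must be present")
  s <- sort(unique(scores))
  thr <- rev(c(-Inf, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, Inf))
  sens <- vapply(thr, function(t) sum(scores >= t & labels == "case") / n_case,
                 numeric(1))
  spec <- vapply(thr, function(t)
    sum(scores < t & labels == "control") / n_ctrl, numeric(1))
  fpr <- 1 - spec
  auc <- sum(diff(fpr) * (sens[-1] + sens[-length(sens)]) / 2)
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d thresholds, AUC = %.3f\n",
              length(x$thresholds), x$auc))
  invisible(x)
}

#' Select the operating cutoff of a ROC curve
#'
#' The threshold where sensitivity and specificity intersect: it minimizes
#' `|sensitivity - specificity|`, ties broken by maximal
#' `sensitivity + specificity`, then by the smaller threshold. Infinite
#' sentinel thresholds are never selected.
#'
#' @param rc a `roc_curve`.
#' @return list with `cutoff`, `sensitivity`, `specificity`.
#' @export
select_cutoff <- function(rc) {
  stopifnot(inherits(rc, "roc_curve"))
  ok <- is.finite(rc$thresholds)
  if (!any(ok)) stopf("degenerate ROC curve")
  thr <- rc$thresholds[ok]
  sens <- rc$sensitivity[ok]
  spec <- rc$specificity[ok]
  gap <- abs(sens - spec)
  best <- which(gap == min(gap))
  if (length(best) > 1L) {
    tot <- sens[best] + spec[best]
    best <- best[tot == max(tot)]
    best <- best[which.min(thr[best])]
  }
  list(cutoff = thr[best], sensitivity = sens[best], specificity = spec[best])
}

stratified_folds <- function(labels, k, seed) {
  local_seed(seed, {
    fold <- integer(length(labels))
    for (lev in unique(labels)) {
      idx <- sample(which(labels == lev))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Stratified k-fold cross-validation of the PMI
#'
#' Splits samples into `k` class-stratified folds. With `reselect = TRUE`
#' (default) the discriminant genera are re-selected by [lefse()] and the
#' index rebuilt inside every training split, so the pooled held-out ROC is
#' free of feature-selection leakage; with `reselect = FALSE` a fixed index
#' is evaluated on the held-out folds.
#'
#' @param x genus-level relative `abundance_table`.
#' @param metadata `sample_metadata` for the table's samples.
#' @param k number of folds.
#' @param seed integer seed (fold assignment and per-fold selection).
#' @param reselect re-run feature selection per training split.
#' @param idx an `index_definition`, required when `reselect = FALSE`.
#' @param alpha,lda_threshold,n_boot passed to [lefse()] when reselecting.
#' @return list of class `cv_result` with `folds` (assignment per sample),
#'   `scores` (pooled held-out scores), `labels`, `roc` (pooled
#'   `roc_curve`), and `fold_indices`.
#' @export
cross_validate <- function(x, metadata, k = 10L, seed = 1L, reselect = TRUE,
                           idx = NULL, alpha = 0.05, lda_threshold = 2.0,
                           n_boot = 30L) {
  stopifnot(inherits(x, "abundance_table"))
  md <- metadata[match(sample_ids(x), metadata$sample_id), ]
  if (anyNA(md$sample_id)) stopf("metadata missing for some samples")
  if (any(table(md$group) < k))
    stopf("a class has fewer than k = %d samples; use a smaller k", k)
  if (!reselect && is.null(idx))
    stopf("reselect = FALSE requires a fixed index definition")
  fold <- stratified_folds(md$group, k, derive_seed(seed, "folds"))
  scores <- stats::setNames(numeric(ncol(x$counts)), sample_ids(x))
  for (f in seq_len(k)) {
    test_i <- which(fold == f)
    train_i <- which(fold != f)
    use_idx <- idx
    if (reselect) {
      tr <- abundance_table(x$counts[, train_i, drop = FALSE],
                            x$lineages, x$type)
      feats <- lefse(tr, md[train_i, ], alpha = alpha,
                     lda_threshold = lda_threshold, n_boot = n_boot,
                     seed = derive_seed(seed, paste0("fold", f)))
      use_idx <- define_index(feats)
    }
    te <- abundance_table(x$counts[, test_i, drop = FALSE],
                          x$lineages, x$type)
    scores[test_i] <- compute_pmi(te, use_idx)
  }
  structure(list(folds = fold, scores = scores, labels = md$group,
                 roc = roc_curve(scores, md$group), k = k, seed = seed,
                 reselect = reselect),
            class = "cv_result")
}

#' Apply a frozen index and cutoff to a cohort
#'
#' Scores every sample with a fixed `index_definition`, classifies at the
#' frozen cutoff (case when `score >= cutoff`), and reports sensitivity,
#' specificity and the cohort's own AUC.
#'
#' @param x genus-level relative `abundance_table` of the test cohort.
#' @param idx a frozen `index_definition` from a training cohort.
#' @param cutoff frozen score cutoff from the training cohort.
#' @param metadata `sample_metadata` of the test cohort.
#' @param provenance recorded origin of the evaluation.
#' @return list of class `index_evaluation` with `scores`, `cutoff`,
#'   `sensitivity`, `specificity`, `auc`, `provenance`.
#' @export
apply_index <- function(x, idx, cutoff, metadata,
                        provenance = c("external", "training",
                                       "cross_validation")) {
  provenance <- match.arg(provenance)
  md <- metadata[match(sample_ids(x), metadata$sample_id), ]
  if (anyNA(md$sample_id)) stopf("metadata missing for some samples")
  scores <- compute_pmi(x, idx)
  case <- md$group == "case"
  structure(list(scores = scores, cutoff = cutoff,
                 sensitivity = mean(scores[case] >= cutoff),
                 specificity = mean(scores[!case] < cutoff),
                 auc = roc_curve(scores, md$group)$auc,
                 provenance = provenance),
            class = "index_evaluation")
}

#' @export
print.index_evaluation <- function(x, ...) {
  cat(sprintf(
    "PMI evaluation (%s): AUC = %.3f; at cutoff %.3f sens = %.3f, spec = %.3f\n",
    x$provenance, x$auc, x$cutoff, x$sensitivity, x$specificity))
  invisible(x)
}
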