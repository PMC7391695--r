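#' Kruskal-Wallis rank-sum test across groups
#'
#' Tie-corrected H statistic with a chi-square p-value on `k - 1` degrees of
#' freedom. When every observation is identical the test is degenerate; by
#' convention `H = 0`, `p = 1` and the result is flagged.
#'
#' @param values numeric observations.
#' @param groups group label per observation (>= 2 groups, >= 2 each).
#' @return list with `H`, `p_value`, `degenerate`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L || any(table(groups) < 2L))
    stopf("need >= 2 groups with >= 2 observations each")
  if (length(unique(values)) == 1L)
    return(list(H = 0, p_value = 1, degenerate = TRUE))
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), p_value = kt$p.value, degenerate = FALSE)
}

#' Bonferroni multiple-testing adjustment
#'
#' `min(1, m * p)` elementwise, with `m` the number of tests.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and names.
#' @export
bonferroni <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "bonferroni")
}

phylum_sums <- function(x, phylum) {
  sel <- x$lineages$phylum == phylum
  colSums(x$counts[sel, , drop = FALSE])
}

#' Firmicutes:Bacteroidetes ratio comparison
#'
#' Per-sample ratio of summed Firmicutes abundance over summed Bacteroidetes
#' abundance (a pseudocount of half the smallest nonzero per-sample phylum
#' sum is used where a denominator is zero), with group means, SDs and a
#' two-sided comparison test.
#'
#' @param x an `abundance_table` with lineages resolving both phyla.
#' @param metadata a `sample_metadata` aligned with the table's samples.
#' @param test `"wilcox"` (Mann-Whitney, default) or `"t"` (Welch).
#' @return list of class `fb_ratio_result` with per-sample `ratios`, a
#'   `by_group` summary (mean, sd, n) and `p_value`.
#' @export
fb_ratio <- function(x, metadata, test = c("wilcox", "t")) {
  stopifnot(inherits(x, "abundance_table"))
  test <- match.arg(test)
  md <- metadata[match(sample_ids(x), metadata$sample_id), ]
  if (anyNA(md$sample_id)) stopf("metadata missing for some samples")
  for (ph in c("Firmicutes", "Bacteroidetes"))
    if (!any(x$lineages$phylum == ph))
      stopf("phylum %s absent from the table", ph)
  f <- phylum_sums(x, "Firmicutes")
  b <- phylum_sums(x, "Bacteroidetes")
  nz <- c(f[f > 0], b[b > 0])
  eps <- min(nz) / 2
  ratios <- (f + eps * (f == 0)) / (b + eps * (b == 0))
  by_group <- do.call(rbind, lapply(split(ratios, md$group), function(v)
    data.frame(mean = mean(v), sd = stats::sd(v), n = length(v))))
  p <- if (test == "wilcox")
    stats::wilcox.test(ratios ~ factor(md$group), exact = FALSE)$p.value
  else stats::t.test(ratios ~ factor(md$group))$p.value
  structure(list(ratios = stats::setNames(ratios, sample_ids(x)),
                 by_group = by_group, test = test, p_value = p),
            class = "fb_ratio_result")
}

#' @export
print.fb_ratio_result <- function(x, ...) {
  cat("Firmicutes:Bacteroidetes ratio\n")
  print(round(x$by_group, 3))
  cat(sprintf("%s test p = %.4g\n",
              if (x$test == "wilcox") "Mann-Whitney" else "Welch t", x$p_value))
  invisible(x)
}

#' LEfSe-style differential genus selection
#'
#' Two-stage effect-size procedure for two-class designs, after Segata et
#' al.'s LDA effect size method: (1) per-genus Kruskal-Wallis screen at
#' `alpha` on per-million-scaled relative abundances; (2) for the survivors,
#' `n_boot` rounds of a one-component linear discriminant on 2/3 class-wise
#' subsamples. The per-round effect size of a genus averages the magnitude
#' of its raw class-mean difference with its share of the class-mean
#' difference along the discriminant axis; the reported score is
#' `log10(1 + mean effect)` and genera are kept when the score reaches
#' `lda_threshold`. Direction is the sign of the case-minus-control mean.
#'
#' @param x an `abundance_table` of genus-level proportions (any per-sample
#'   scaling is accepted; samples are renormalized to one million).
#' @param metadata a `sample_metadata` covering the table's samples.
#' @param alpha Kruskal-Wallis screen level.
#' @param lda_threshold minimum log10 LDA score to report.
#' @param n_boot number of discriminant bootstrap rounds.
#' @param seed integer seed.
#' @return data.frame of class `differential_features` with columns `genus`,
#'   `direction` (`case_enriched`/`control_enriched`), `kw_p`, `lda_score`,
#'   ordered by decreasing score.
#' @export
lefse <- function(x, metadata, alpha = 0.05, lda_threshold = 2.0,
                  n_boot = 30L, seed = 1L) {
  stopifnot(inherits(x, "abundance_table"))
  md <- metadata[match(sample_ids(x), metadata$sample_id), ]
  if (anyNA(md$sample_id)) stopf("metadata missing for some samples")
  cls <- factor(md$group, levels = c("control", "case"))
  if (any(table(cls) < 3L)) stopf("each class needs at least 3 samples")
  # per-million scaling makes the score scale-invariant
  m <- sweep(x$counts, 2L, colSums(x$counts), "/") * 1e6
  kw_p <- apply(m, 1L, function(v) kruskal_wallis(v, cls)$p_value)
  surv <- which(kw_p < alpha)
  empty <- structure(
    data.frame(genus = character(), direction = character(),
               kw_p = numeric(), lda_score = numeric(),
               stringsAsFactors = FALSE),
    class = c("differential_features", "data.frame"))
  if (!length(surv)) return(empty)
  feats <- t(m[surv, , drop = FALSE])  # samples x features
  effects <- local_seed(seed, lda_effect_sizes(feats, cls, n_boot))
  score <- log10(1 + effects)
  diff_means <- colMeans(feats[cls == "case", , drop = FALSE]) -
    colMeans(feats[cls == "control", , drop = FALSE])
  keep <- which(score >= lda_threshold)
  if (!length(keep)) return(empty)
  out <- data.frame(
    genus = colnames(feats)[keep],
    direction = ifelse(diff_means[keep] > 0, "case_enriched",
                       "control_enriched"),
    kw_p = unname(kw_p[surv][keep]),
    lda_score = unname(score[keep]),
    stringsAsFactors = FALSE)
  out <- out[order(-out$lda_score), ]
  rownames(out) <- NULL
  class(out) <- c("differential_features", "data.frame")
  out
}

# Bootstrapped one-component LDA effect sizes (per feature): each round
# subsamples 2/3 of each class, fits MASS::lda, and combines the raw
# class-mean difference with the feature's contribution to the separation
# along the unit discriminant axis.
lda_effect_sizes <- function(feats, cls, n_boot) {
  idx_by_class <- split(seq_len(nrow(feats)), cls)
  p <- ncol(feats)
  acc <- matrix(NA_real_, n_boot, p)
  for (b in seq_len(n_boot)) {
    sub <- unlist(lapply(idx_by_class, function(ix)
      sample(ix, max(2L, floor(2 / 3 * length(ix))))), use.names = FALSE)
    xs <- feats[sub, , drop = FALSE]
    ys <- cls[sub]
    gm <- abs(colMeans(xs[ys == "case", , drop = FALSE]) -
                colMeans(xs[ys == "control", , drop = FALSE]))
    # jitter constant-within-class columns so lda() stays well-posed
    wvar <- apply(xs, 2L, function(v) max(tapply(v, ys, stats::var)))
    flat <- which(!is.finite(wvar) | wvar < 1e-10)
    if (length(flat))
      xs[, flat] <- xs[, flat] +
        matrix(stats::rnorm(nrow(xs) * length(flat), 0, 1e-5),
               nrow(xs), length(flat))
    coeff <- rep(0, p)
    fit <- try(suppressWarnings(MASS::lda(xs, grouping = ys, tol = 1e-10)),
               silent = TRUE)
    if (!inherits(fit, "try-error")) {
      w <- fit$scaling[, 1L]
      w <- w / sqrt(sum(w^2))
      ld <- drop(xs %*% w)
      sep <- abs(mean(ld[ys == "case"]) - mean(ld[ys == "control"]))
      coeff <- abs(w) * sep
    }
    acc[b, ] <- (gm + coeff) / 2
  }
  colMeans(acc)
}
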