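#' Chao1 richness estimator
#'
#' Bias-corrected Chao1: `S_obs + F1*(F1-1) / (2*(F2+1))` where `F1` and
#' `F2` are the numbers of singleton and doubleton taxa. Always at least the
#' observed richness.
#'
#' @param counts non-negative integer vector of taxon counts for one sample.
#' @return the richness estimate (numeric scalar).
#' @examples
#' chao1(c(5, 3, 1, 1, 2)) # 5 + 2*1/(2*2) = 5.5
#' @export
chao1 <- function(counts) {
  if (any(counts < 0) || any(counts != round(counts)))
    stopf("counts must be non-negative integers")
  if (all(counts == 0)) stopf("cannot estimate richness of an all-zero sample")
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Rarefy a count vector to a fixed depth
#'
#' Subsamples reads without replacement so that the total equals `depth`.
#'
#' @param counts non-negative integer vector.
#' @param depth target total (<= `sum(counts)`).
#' @param seed integer seed.
#' @return integer vector of the same length and names, summing to `depth`.
#' @export
rarefy <- function(counts, depth, seed = 1L) {
  if (any(counts < 0) || any(counts != round(counts)))
    stopf("counts must be non-negative integers")
  if (depth > sum(counts))
    stopf("depth %d exceeds sample total %d", depth, sum(counts))
  if (depth == 0) return(stats::setNames(integer(length(counts)), names(counts)))
  local_seed(seed, {
    reads <- rep.int(seq_along(counts), counts)
    keep <- sample(reads, depth)
    stats::setNames(tabulate(keep, nbins = length(counts)), names(counts))
  })
}

#' Compare alpha diversity between two groups
#'
#' Computes per-sample Chao1 richness at a common rarefaction depth and
#' compares two groups with a two-sided Mann-Whitney U test (default) or
#' Welch t-test.
#'
#' @param x an `abundance_table` of counts.
#' @param labels character/factor of group labels, one per sample (exactly
#'   two distinct values among the samples compared; samples with `NA` label
#'   are dropped).
#' @param test `"wilcox"` or `"t"`.
#' @param depth rarefaction depth; default is the minimum per-sample total.
#' @param seed integer seed for rarefaction.
#' @return list with per-sample `chao1`, the `depth` used, and `p_value`.
#' @export
compare_alpha_diversity <- function(x, labels, test = c("wilcox", "t"),
                                    depth = NULL, seed = 1L) {
  stopifnot(inherits(x, "abundance_table"), x$type == "counts")
  test <- match.arg(test)
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(x$counts))
  keep <- !is.na(labels)
  m <- x$counts[, keep, drop = FALSE]
  labels <- labels[keep]
  if (length(unique(labels)) != 2L) stopf("need exactly two groups")
  depth <- depth %||% min(colSums(m))
  vals <- vapply(seq_len(ncol(m)), function(j)
    chao1(rarefy(m[, j], depth, seed = derive_seed(seed, colnames(m)[j]))),
    numeric(1))
  names(vals) <- colnames(m)
  p <- if (test == "wilcox")
    stats::wilcox.test(vals ~ factor(labels), exact = FALSE)$p.value
  else stats::t.test(vals ~ factor(labels))$p.value
  list(chao1 = vals, depth = depth, labels = labels, test = test, p_value = p)
}

# --- UniFrac machinery -------------------------------------------------------

# Edge-by-tip incidence of a rooted ape::phylo: M[e, t] is TRUE when tip t
# descends through edge e. Computed once per tree by postorder accumulation.
edge_tip_incidence <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stopf("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stopf("negative branch length in tree")
  if (anyDuplicated(tree$tip.label)) stopf("duplicate tip labels in tree")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  tree <- stats::reorder(tree, "postorder")
  desc <- matrix(FALSE, nnode, ntip)
  desc[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  for (k in seq_len(nrow(tree$edge))) {
    e <- tree$edge[k, ]
    desc[e[1], ] <- desc[e[1], ] | desc[e[2], ]
  }
  M <- desc[tree$edge[, 2], , drop = FALSE]
  colnames(M) <- tree$tip.label
  list(incidence = M, lengths = tree$edge.length)
}

# Map a named abundance vector onto tree tip order; taxa with nonzero
# abundance must be tree leaves.
tip_vector <- function(tree, x) {
  v <- stats::setNames(numeric(length(tree$tip.label)), tree$tip.label)
  miss <- setdiff(names(x)[x > 0], tree$tip.label)
  if (length(miss))
    stopf("taxon not in tree: %s", paste(miss, collapse = ", "))
  common <- intersect(names(x), tree$tip.label)
  v[common] <- x[common]
  v
}

#' UniFrac phylogenetic distances between two communities
#'
#' `unweighted_unifrac()` is the fraction of branch length leading
#' exclusively to taxa present in only one of the two samples, out of the
#' branch length leading to taxa present in either. `weighted_unifrac()`
#' weights each branch by the absolute difference of the proportions of each
#' community descending through it (`sum(len * |A - B|)`); with
#' `normalized = TRUE` it is divided by its maximum attainable value on the
#' tree, `sum(len * (A + B))`.
#'
#' @param tree a rooted `ape::phylo` with branch lengths whose tips cover
#'   all non-zero taxa of the samples.
#' @param a,b named non-negative abundance vectors (counts or proportions).
#' @param normalized divide the weighted distance by its tree-wise maximum.
#' @return a non-negative distance; unweighted and normalized weighted are
#'   in `[0, 1]`.
#' @export
unweighted_unifrac <- function(tree, a, b) {
  et <- edge_tip_incidence(tree)
  pa <- drop(et$incidence %*% (tip_vector(tree, a) > 0)) > 0
  pb <- drop(et$incidence %*% (tip_vector(tree, b) > 0)) > 0
  union <- sum(et$lengths[pa | pb])
  if (union == 0) return(0)
  sum(et$lengths[xor(pa, pb)]) / union
}

#' @rdname unweighted_unifrac
#' @export
weighted_unifrac <- function(tree, a, b, normalized = FALSE) {
  va <- tip_vector(tree, a)
  vb <- tip_vector(tree, b)
  if (sum(va) == 0 || sum(vb) == 0) stopf("zero-total sample")
  et <- edge_tip_incidence(tree)
  A <- drop(et$incidence %*% (va / sum(va)))
  B <- drop(et$incidence %*% (vb / sum(vb)))
  d <- sum(et$lengths * abs(A - B))
  if (normalized) d <- d / sum(et$lengths * (A + B))
  d
}

#' Pairwise UniFrac distance matrix for an abundance table
#'
#' Computes all pairwise distances with a single per-edge accumulation pass,
#' equivalent to calling the pairwise functions on every sample pair.
#'
#' @param x an `abundance_table` (counts or proportions).
#' @param tree rooted `ape::phylo` covering the table's non-zero taxa.
#' @param metric one of `"unweighted_unifrac"`, `"weighted_unifrac"`,
#'   `"weighted_unifrac_normalized"`.
#' @return a symmetric `distance_matrix` (square numeric matrix, zero
#'   diagonal, sample ids as dimnames).
#' @export
distance_matrix <- function(x, tree,
                            metric = c("weighted_unifrac",
                                       "unweighted_unifrac",
                                       "weighted_unifrac_normalized")) {
  stopifnot(inherits(x, "abundance_table"))
  metric <- match.arg(metric)
  et <- edge_tip_incidence(tree)
  P <- vapply(seq_len(ncol(x$counts)),
              function(j) tip_vector(tree, x$counts[, j]),
              numeric(length(tree$tip.label)))
  colnames(P) <- sample_ids(x)
  if (metric == "unweighted_unifrac") {
    Bm <- (et$incidence %*% (P > 0)) > 0
    W <- et$lengths * Bm
    xor_d <- as.matrix(stats::dist(t(W), method = "manhattan"))
    s <- colSums(W)
    union <- (outer(s, s, "+") + xor_d) / 2
    D <- ifelse(union == 0, 0, xor_d / union)
  } else {
    tot <- colSums(P)
    if (any(tot == 0))
      stopf("zero-total sample: %s",
            paste(colnames(P)[tot == 0], collapse = ", "))
    E <- et$incidence %*% sweep(P, 2L, tot, "/")
    W <- et$lengths * E
    D <- as.matrix(stats::dist(t(W), method = "manhattan"))
    if (metric == "weighted_unifrac_normalized") {
      s <- colSums(W)
      D <- D / outer(s, s, "+")
    }
  }
  diag(D) <- 0
  dimnames(D) <- list(sample_ids(x), sample_ids(x))
  class(D) <- c("distance_matrix", class(D))
  D
}

as_square_distance <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-12)
    stopf("distance matrix must be square and symmetric")
  if (any(diag(m) != 0)) stopf("distance matrix diagonal must be zero")
  m
}

#' Principal coordinates analysis
#'
#' Classical metric scaling: Gower double-centering of `-D^2/2` followed by
#' an eigendecomposition. Axes with positive eigenvalues carry coordinates;
#' negative eigenvalues are reported but excluded from the
#' proportion-explained denominator.
#'
#' @param d a `distance_matrix`, `dist`, or symmetric matrix.
#' @return list of class `ordination` with `points` (samples x axes),
#'   `eigenvalues` (all, decreasing) and `proportion_explained`.
#' @export
pcoa <- function(d) {
  m <- as_square_distance(d)
  if (nrow(m) < 2L) stopf("need at least 2 samples")
  n <- nrow(m)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (m * m) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- which(e$values > tol)
  pts <- matrix(0, n, length(pos),
                dimnames = list(rownames(m),
                                if (length(pos)) paste0("PCo", seq_along(pos))))
  if (length(pos))
    pts[] <- e$vectors[, pos, drop = FALSE] %*%
      diag(sqrt(e$values[pos]), length(pos))
  structure(list(points = pts, eigenvalues = e$values,
                 proportion_explained = e$values[pos] / sum(e$values[pos])),
            class = "ordination")
}

#' PERMANOVA (ADONIS) on a distance matrix
#'
#' One-factor permutational multivariate analysis of variance in the
#' Anderson (2001) form: the total sum of squared distances is partitioned
#' into within- and between-group components, and the pseudo-F statistic is
#' referred to its permutation distribution under random relabelling.
#'
#' @param d distance matrix (`distance_matrix`, `dist`, or symmetric matrix).
#' @param groups group label per sample (>= 2 groups of >= 2 samples).
#' @param n_permutations number of label permutations.
#' @param seed integer seed for the permutations.
#' @return list of class `permanova_result` with `pseudo_F`, `p_value`,
#'   `n_permutations` and `seed`. `p_value` is
#'   `(1 + #permuted F >= observed) / (1 + n_permutations)`.
#' @export
permanova <- function(d, groups, n_permutations = 999, seed = 1L) {
  m <- as_square_distance(d)
  groups <- factor(groups)
  if (length(groups) != nrow(m)) stopf("one group label per sample required")
  if (nlevels(groups) < 2L || any(table(groups) < 2L))
    stopf("need >= 2 groups with >= 2 samples each")
  n <- nrow(m)
  a <- nlevels(groups)
  d2 <- m * m
  ss_total <- sum(d2[upper.tri(d2)]) / n
  f_stat <- function(g) {
    within <- 0
    for (idx in split(seq_len(n), g))
      within <- within + sum(d2[idx, idx]) / (2 * length(idx))
    ss_a <- ss_total - within
    (ss_a / (a - 1)) / (within / (n - a))
  }
  f_obs <- f_stat(groups)
  exceed <- local_seed(seed, {
    sum(vapply(seq_len(n_permutations),
               function(i) f_stat(sample(groups)), numeric(1)) >= f_obs)
  })
  structure(list(pseudo_F = f_obs,
                 p_value = (1 + exceed) / (1 + n_permutations),
                 n_permutations = n_permutations, seed = seed),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4f, p = %.4g (%d permutations)\n",
              x$pseudo_F, x$p_value, x$n_permutations))
  invisible(x)
}
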