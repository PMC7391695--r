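# Shared fixtures and independent oracles.

tiny_table <- function() {
  m <- matrix(c(5, 0, 2, 1, 3, 4), nrow = 3, byrow = TRUE,
              dimnames = list(c("otu1", "otu2", "otu3"), c("s1", "s2")))
  lin <- c(
    otu1 = "k__Bacteria; p__Firmicutes; c__Clostridia; o__Clostridiales; f__Lachnospiraceae; g__Blautia",
    otu2 = "k__Bacteria; p__Firmicutes; c__Clostridia; o__Clostridiales; f__Lachnospiraceae; g__Blautia",
    otu3 = "k__Bacteria; p__Bacteroidetes; c__Bacteroidia; o__Bacteroidales; f__Bacteroidaceae; g__Bacteroides")
  abundance_table(m, lin)
}

random_table <- function(seed, n_taxa = 8, n_samples = 5) {
  set.seed(seed)
  m <- matrix(rpois(n_taxa * n_samples, 20), n_taxa, n_samples,
              dimnames = list(paste0("t", seq_len(n_taxa)),
                              paste0("s", seq_len(n_samples))))
  genera <- paste0("Genus", sample(ceiling(n_taxa / 2), n_taxa, replace = TRUE))
  phyla <- sample(c("Firmicutes", "Bacteroidetes"), n_taxa, replace = TRUE)
  lin <- sprintf("k__Bacteria; p__%s; c__C; o__O; f__F; g__%s", phyla, genera)
  abundance_table(m, setNames(lin, rownames(m)))
}

# --- independent UniFrac oracle ---------------------------------------------
# Walks every edge, collects descendant tips by direct recursion over the
# edge list, and accumulates shared/unique branch lengths; independent of the
# package's incidence-matrix implementation.
tips_below <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, tips_below, tree = tree))
}

oracle_unifrac <- function(tree, a, b, weighted = FALSE, normalized = FALSE) {
  full <- function(x) {
    v <- setNames(numeric(length(tree$tip.label)), tree$tip.label)
    v[names(x)] <- x
    v
  }
  av <- full(a); bv <- full(b)
  if (weighted) { av <- av / sum(av); bv <- bv / sum(bv) }
  num <- den <- 0
  for (k in seq_len(nrow(tree$edge))) {
    tips <- tips_below(tree, tree$edge[k, 2])
    len <- tree$edge.length[k]
    if (weighted) {
      A <- sum(av[tips]); B <- sum(bv[tips])
      num <- num + len * abs(A - B)
      den <- den + len * (A + B)
    } else {
      pa <- sum(av[tips]) > 0; pb <- sum(bv[tips]) > 0
      if (xor(pa, pb)) num <- num + len
      if (pa || pb) den <- den + len
    }
  }
  if (weighted) { if (normalized) num / den else num }
  else if (den == 0) 0 else num / den
}

# --- independent AUC oracle: exhaustive pairwise concordance ----------------
oracle_auc <- function(scores, labels) {
  cs <- scores[labels == "case"]
  cn <- scores[labels == "control"]
  tot <- 0
  for (x in cs) for (y in cn)
    tot <- tot + if (x > y) 1 else if (x == y) 0.5 else 0
  tot / (length(cs) * length(cn))
}

random_labelled_scores <- function(seed, n, tie_prone = TRUE) {
  set.seed(seed)
  repeat {
    labels <- sample(c("case", "control"), n, replace = TRUE)
    if (length(unique(labels)) == 2) break
  }
  scores <- if (tie_prone) sample(1:3, n, replace = TRUE) else rnorm(n)
  list(scores = scores, labels = labels)
}
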