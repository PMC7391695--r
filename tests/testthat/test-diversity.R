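test_that("Chao1 reproduces closed-form values and bounds observed richness", {
  expect_equal(chao1(c(5, 3, 1, 1, 2)), 5.5)   # S=5, F1=2, F2=1
  expect_equal(chao1(c(1, 1, 1)), 6.0)         # F2=0 handled by +1 correction
  expect_equal(chao1(c(5, 3, 2, 2)), 4)        # no singletons -> S_obs
  expect_error(chao1(c(0, 0)), "all-zero")
  expect_error(chao1(c(1.5, 2)), "integers")

  set.seed(1)
  for (i in 1:20) {
    v <- rpois(30, 2)
    if (all(v == 0)) next
    expect_gte(chao1(v), sum(v > 0))
  }
})

test_that("rarefaction subsamples without replacement at the target depth", {
  x <- c(a = 10, b = 5, c = 0, d = 1)
  expect_equal(sort(unname(rarefy(x, 16, seed = 1))), sort(unname(x)))
  expect_equal(rarefy(x, 0), setNames(c(0L, 0L, 0L, 0L), names(x)))
  expect_error(rarefy(x, 17), "exceeds")

  r <- rarefy(x, 8, seed = 2)
  expect_equal(sum(r), 8)
  expect_true(all(r <= x))

  # expected rarefied count ~ depth * proportion
  means <- rowMeans(vapply(1:1000, function(s) rarefy(x, 8, seed = s),
                           numeric(4)))
  expect_equal(unname(means), 8 * unname(x) / sum(x), tolerance = 0.05)
})

test_that("alpha-diversity group comparison runs both tests", {
  co <- generate_cohort(default_psoriasis_config(seed = 9, n_cases = 10,
                                                 n_controls = 10))
  res <- compare_alpha_diversity(co$table, co$metadata$group, seed = 1)
  expect_length(res$chao1, 20)
  expect_true(res$p_value >= 0 && res$p_value <= 1)
  res_t <- compare_alpha_diversity(co$table, co$metadata$group, test = "t",
                                   seed = 1)
  expect_equal(res_t$chao1, res$chao1)  # same rarefaction, different test
})

test_that("UniFrac matches hand values on small trees", {
  # 4-leaf balanced tree, unit branches
  tr <- ape::read.tree(text = "((L1:1,L2:1):1,(L3:1,L4:1):1);")
  a <- c(L1 = 1, L2 = 1)
  b <- c(L3 = 1)
  # unique: L1,L2 edges + (L1,L2) stem + L3 edge + (L3,L4) stem = 5
  # union adds nothing shared -> 5/5
  expect_equal(unweighted_unifrac(tr, a, b), 1)
  b2 <- c(L2 = 1, L3 = 1)
  # shared: L2 edge; unique: L1, stem12, L3, stem34... edge walk via oracle
  expect_equal(unweighted_unifrac(tr, a, b2), oracle_unifrac(tr, a, b2))

  expect_equal(unweighted_unifrac(tr, a, a), 0)
  expect_equal(weighted_unifrac(tr, a, a), 0)

  # star-like disjoint sets -> unweighted 1
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  expect_equal(unweighted_unifrac(star, c(A = 2, B = 1), c(C = 5, D = 1)), 1)

  # two-leaf cherry, unit branches, disjoint -> raw weighted distance 2
  cherry <- ape::read.tree(text = "(t1:1,t2:1);")
  expect_equal(weighted_unifrac(cherry, c(t1 = 3), c(t2 = 7)), 2)
  expect_equal(weighted_unifrac(cherry, c(t1 = 3), c(t2 = 7),
                                normalized = TRUE), 1)

  expect_error(weighted_unifrac(tr, c(L9 = 1), b), "L9")
  expect_error(weighted_unifrac(tr, c(L1 = 0), b), "zero-total")
})

test_that("UniFrac agrees with the edge-walk oracle on random trees", {
  for (seed in 1:25) {
    n <- sample(3:8, 1)
    tr <- generate_tree(paste0("x", seq_len(n)), seed = seed)
    set.seed(seed + 100)
    a <- setNames(rpois(n, 3), tr$tip.label)
    b <- setNames(rpois(n, 3), tr$tip.label)
    if (sum(a) == 0 || sum(b) == 0) next
    expect_equal(unweighted_unifrac(tr, a, b), oracle_unifrac(tr, a, b),
                 tolerance = 1e-12)
    expect_equal(weighted_unifrac(tr, a, b),
                 oracle_unifrac(tr, a, b, weighted = TRUE), tolerance = 1e-12)
    expect_equal(weighted_unifrac(tr, a, b, normalized = TRUE),
                 oracle_unifrac(tr, a, b, weighted = TRUE, normalized = TRUE),
                 tolerance = 1e-12)
  }
})

test_that("unweighted UniFrac agrees with picante on a shared fixture", {
  skip_if_not_installed("picante")
  tr <- generate_tree(paste0("t", 1:7), seed = 3)
  set.seed(99)
  comm <- matrix(rpois(21, 2), 3, 7,
                 dimnames = list(paste0("s", 1:3), tr$tip.label))
  comm[comm > 0] <- 1
  ours <- sapply(1:3, function(i) sapply(1:3, function(j)
    unweighted_unifrac(tr, comm[i, ], comm[j, ])))
  ref <- as.matrix(picante::unifrac(comm, tr))
  expect_equal(unname(ours), unname(ref[paste0("s", 1:3), paste0("s", 1:3)]),
               tolerance = 1e-10)
})

test_that("distance_matrix matches pairwise calls and is symmetric", {
  co <- generate_cohort(default_psoriasis_config(seed = 2, n_cases = 4,
                                                 n_controls = 4))
  tr <- generate_tree(rownames(co$table$counts), seed = 2)
  for (metric in c("unweighted_unifrac", "weighted_unifrac",
                   "weighted_unifrac_normalized")) {
    D <- distance_matrix(co$table, tr, metric)
    expect_equal(unname(D), unname(t(D)), tolerance = 1e-12)
    expect_equal(unname(diag(D)), rep(0, 8))
    fn <- switch(metric,
                 unweighted_unifrac = function(a, b) unweighted_unifrac(tr, a, b),
                 weighted_unifrac = function(a, b) weighted_unifrac(tr, a, b),
                 weighted_unifrac_normalized =
                   function(a, b) weighted_unifrac(tr, a, b, normalized = TRUE))
    for (i in c(1, 3)) for (j in c(2, 7))
      expect_equal(D[i, j], fn(co$table$counts[, i], co$table$counts[, j]),
                   tolerance = 1e-12)
  }

  one <- abundance_table(co$table$counts[, 1, drop = FALSE], co$table$lineages)
  D1 <- distance_matrix(one, tr)
  expect_equal(unname(as.matrix(D1)), matrix(0, 1, 1))
})

test_that("PCoA embeds distances and rejects asymmetric input", {
  # 3 collinear points at 0, 1, 3
  d <- as.matrix(dist(c(0, 1, 3)))
  ord <- pcoa(d)
  expect_equal(unname(as.matrix(dist(ord$points[, 1]))), unname(d),
               tolerance = 1e-8)
  expect_true(all(diff(ord$eigenvalues) <= 1e-8))

  z <- matrix(0, 3, 3)
  expect_equal(ncol(pcoa(z)$points), 0L)  # no positive axis: all coords zero

  # full-rank Euclidean reconstruction
  set.seed(5)
  pts <- matrix(rnorm(12), 4, 3)
  d4 <- as.matrix(dist(pts))
  ord4 <- pcoa(d4)
  expect_equal(unname(as.matrix(dist(ord4$points))), unname(d4),
               tolerance = 1e-8)
  expect_equal(sum(ord4$proportion_explained), 1)

  bad <- d; bad[1, 2] <- 99
  expect_error(pcoa(bad), "symmetric")
})

test_that("PCoA agrees with classical cmdscale", {
  set.seed(8)
  d <- as.matrix(dist(matrix(rnorm(20), 5, 4)))
  ours <- pcoa(d)$points
  ref <- cmdscale(d, k = 4)
  expect_equal(abs(unname(ours)), abs(unname(ref)), tolerance = 1e-8)
})

test_that("PERMANOVA behaves at the extremes and matches vegan", {
  # two tight clusters far apart: p attains the permutation floor (no
  # permuted relabelling reproduces the split at these group sizes)
  m <- matrix(0, 20, 20)
  m[1:10, 11:20] <- 10; m[11:20, 1:10] <- 10
  res <- permanova(m, rep(c("a", "b"), each = 10), n_permutations = 99,
                   seed = 1)
  expect_equal(res$p_value, 1 / 100)

  # observed F invariant under group-name relabelling
  set.seed(2)
  d <- as.matrix(dist(matrix(rnorm(40), 10, 4)))
  g <- rep(c("x", "y"), 5)
  f1 <- permanova(d, g, n_permutations = 9, seed = 1)$pseudo_F
  f2 <- permanova(d, ifelse(g == "x", "B", "A"), n_permutations = 9,
                  seed = 1)$pseudo_F
  expect_equal(f1, f2)

  expect_error(permanova(d, rep(c("x", "y", "z"), c(8, 1, 1)),
                         n_permutations = 9), "2 samples")

  skip_if_not_installed("vegan")
  ref <- vegan::adonis2(as.dist(d) ~ g, permutations = 99)
  expect_equal(f1, ref$F[1], tolerance = 1e-10)
})

test_that("PERMANOVA p-values are seed-stable and on the discrete grid", {
  set.seed(3)
  d <- as.matrix(dist(matrix(rnorm(32), 8, 4)))
  g <- rep(c("u", "v"), each = 4)
  p1 <- permanova(d, g, n_permutations = 199, seed = 7)$p_value
  p2 <- permanova(d, g, n_permutations = 199, seed = 7)$p_value
  expect_identical(p1, p2)
  expect_true(p1 >= 1 / 200 && p1 <= 1)
  expect_equal(p1 * 200, round(p1 * 200))
})
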