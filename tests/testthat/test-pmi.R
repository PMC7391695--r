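features_fixture <- function() {
  data.frame(
    genus = c("Faecalibacterium", "Blautia", "Bacteroides", "Paraprevotella"),
    direction = c("case_enriched", "case_enriched",
                  "control_enriched", "control_enriched"),
    kw_p = c(1e-4, 1e-3, 1e-4, 1e-3),
    lda_score = c(4, 3, 4, 3))
}

genus_fixture <- function(vals) {
  # vals: named list sample -> named genus proportions (must each sum to 1)
  m <- do.call(cbind, vals)
  lin <- setNames(sprintf("k__Bacteria; p__P; c__C; o__O; f__F; g__%s",
                          rownames(m)), rownames(m))
  abundance_table(m, lin, "proportions")
}

test_that("define_index splits features by direction and validates", {
  idx <- define_index(features_fixture())
  expect_equal(idx$increased_genera, c("Blautia", "Faecalibacterium"))
  expect_equal(idx$decreased_genera, c("Bacteroides", "Paraprevotella"))
  expect_equal(idx$log_base, 10)

  two <- define_index(features_fixture()[c(1, 3), ])
  expect_length(two$increased_genera, 1)

  dup <- rbind(features_fixture(),
               data.frame(genus = "Blautia", direction = "control_enriched",
                          kw_p = 0.01, lda_score = 2.5))
  expect_error(define_index(dup), "both directions")
  expect_error(define_index(features_fixture()[1:2, ]), "each direction")
})

test_that("index JSON round-trips", {
  idx <- define_index(features_fixture(), pseudocount = 1e-6)
  tmp <- tempfile(fileext = ".json")
  write_index(idx, tmp)
  expect_equal(read_index(tmp), idx)
})

test_that("compute_pmi evaluates the log-ratio formula", {
  idx <- define_index(features_fixture())
  tab <- genus_fixture(list(
    s1 = c(Faecalibacterium = 0.01, Blautia = 0.01, Bacteroides = 0.15,
           Paraprevotella = 0.05, Other = 0.78),
    s2 = c(Faecalibacterium = 0.1, Blautia = 0.1, Bacteroides = 0.1,
           Paraprevotella = 0.1, Other = 0.6)))
  sc <- compute_pmi(tab, idx)
  expect_equal(unname(sc["s1"]), log10(0.02 / 0.20))  # -1.0
  expect_equal(unname(sc["s2"]), 0)                   # equal sums

  # swapping directions negates every score
  flip <- features_fixture()
  flip$direction <- rev(flip$direction)
  expect_equal(unname(compute_pmi(tab, define_index(flip))), -unname(sc))

  counts <- tab; counts$type <- "counts"
  expect_error(compute_pmi(counts, idx), "relative")
})

test_that("compute_pmi pseudocount handles zero sums and absent genera", {
  idx <- define_index(features_fixture())
  tab <- genus_fixture(list(
    s1 = c(Faecalibacterium = 0, Blautia = 0, Bacteroides = 0.5,
           Paraprevotella = 0, Other = 0.5)))
  sc <- compute_pmi(tab, idx)
  eps <- min(tab$counts[tab$counts > 0]) / 2
  expect_equal(unname(sc), log10(eps / (0.5 + eps)))

  drop_one <- genus_fixture(list(
    s1 = c(Faecalibacterium = 0.2, Bacteroides = 0.4, Other = 0.4)))
  expect_warning(sc2 <- compute_pmi(drop_one, idx), "Blautia")
  expect_equal(unname(sc2), log10(0.2 / 0.4))

  none <- genus_fixture(list(s1 = c(Other = 1)))
  expect_error(suppressWarnings(compute_pmi(none, idx)), "none of the index")
})

test_that("ROC curve matches exhaustive pairwise concordance", {
  sep <- roc_curve(c(3, 4, 5, 0, 1, 2),
                   rep(c("case", "control"), each = 3))
  expect_equal(sep$auc, 1)
  cut <- select_cutoff(sep)
  expect_equal(cut$cutoff, 2.5)  # midpoint of the separating gap
  expect_equal(cut$sensitivity, 1)
  expect_equal(cut$specificity, 1)

  for (seed in 1:30) {
    n <- sample(4:8, 1)
    cfg <- random_labelled_scores(seed, n)
    rc <- roc_curve(cfg$scores, cfg$labels)
    expect_equal(rc$auc, oracle_auc(cfg$scores, cfg$labels),
                 tolerance = 1e-12)
    expect_true(all(diff(rc$sensitivity) >= 0))  # thresholds descending
    expect_true(rc$auc >= 0 && rc$auc <= 1)
  }

  expect_error(roc_curve(1:3, rep("case", 3)), "both classes")
})

test_that("AUC agrees with pROC and is invariant to monotone transforms", {
  skip_if_not_installed("pROC")
  set.seed(10)
  scores <- c(rnorm(20, 1), rnorm(25))
  labels <- rep(c("case", "control"), c(20, 25))
  rc <- roc_curve(scores, labels)
  ref <- suppressMessages(pROC::auc(pROC::roc(labels, scores,
                                              levels = c("control", "case"),
                                              direction = "<")))
  expect_equal(rc$auc, as.numeric(ref), tolerance = 1e-10)

  expect_equal(roc_curve(exp(scores), labels)$auc, rc$auc, tolerance = 1e-12)
  expect_equal(roc_curve(scores * 3 - 7, labels)$auc, rc$auc,
               tolerance = 1e-12)
})

test_that("AUC under label-score independence concentrates on 0.5", {
  set.seed(77)
  scores <- rnorm(4000)
  labels <- sample(rep(c("case", "control"), each = 2000))
  expect_equal(roc_curve(scores, labels)$auc, 0.5, tolerance = 0.03)
})

test_that("select_cutoff minimizes |sens - spec| over all thresholds", {
  set.seed(15)
  scores <- c(rnorm(40, 0.8), rnorm(40, -0.8))  # symmetric overlapping clouds
  labels <- rep(c("case", "control"), each = 40)
  rc <- roc_curve(scores, labels)
  cut <- select_cutoff(rc)
  expect_lt(abs(cut$cutoff), 0.4)
  expect_lt(abs(cut$sensitivity - cut$specificity), 0.1)
  ok <- is.finite(rc$thresholds)
  expect_lte(abs(cut$sensitivity - cut$specificity),
             min(abs(rc$sensitivity[ok] - rc$specificity[ok])))
})

test_that("cross-validation is stratified, reproducible and leak-aware", {
  co <- generate_cohort(default_psoriasis_config(seed = 31, n_cases = 25,
                                                 n_controls = 20))
  rel <- to_relative(collapse_to_rank(co$table, "genus"))
  idx <- define_index(features_fixture())

  cv <- cross_validate(rel, co$metadata, k = 5, seed = 2, reselect = FALSE,
                       idx = idx)
  # fixed index: held-out scores equal plain scoring, so pooled AUC matches
  expect_equal(cv$roc$auc, roc_curve(compute_pmi(rel, idx),
                                     co$metadata$group)$auc)

  cv2 <- cross_validate(rel, co$metadata, k = 5, seed = 2, reselect = FALSE,
                        idx = idx)
  expect_identical(cv$folds, cv2$folds)

  # class proportions per fold within 1 of proportional
  for (f in 1:5) {
    tab <- table(co$metadata$group[cv$folds == f])
    expect_lte(abs(tab[["case"]] - 25 / 5), 1)
    expect_lte(abs(tab[["control"]] - 20 / 5), 1)
  }

  expect_error(cross_validate(rel, co$metadata, k = 30), "smaller k")
  expect_error(cross_validate(rel, co$metadata, k = 5, reselect = FALSE),
               "fixed index")
})

test_that("frozen-index application transfers and inverts as expected", {
  co <- generate_cohort(default_psoriasis_config(seed = 8))
  rel <- to_relative(collapse_to_rank(co$table, "genus"))
  idx <- define_index(features_fixture())
  sc <- compute_pmi(rel, idx)
  cut <- select_cutoff(roc_curve(sc, co$metadata$group))

  self <- apply_index(rel, idx, cut$cutoff, co$metadata,
                      provenance = "training")
  expect_equal(self$sensitivity, cut$sensitivity)
  expect_equal(self$specificity, cut$specificity)

  # inverted effect directions push the AUC below chance
  inv_cfg <- synthetic_cohort_config(
    n_cases = 50, n_controls = 50,
    baseline = pmindex:::psoriasis_baseline(),
    lineages = pmindex:::psoriasis_lineages(),
    effect_multipliers = c(Faecalibacterium = 0.4, Blautia = 0.4,
                           Bacteroides = 2.5, Paraprevotella = 2.5),
    seed = 9)
  inv <- generate_cohort(inv_cfg)
  inv_rel <- to_relative(collapse_to_rank(inv$table, "genus"))
  ev <- apply_index(inv_rel, idx, cut$cutoff, inv$metadata)
  expect_lt(ev$auc, 0.5)
  expect_equal(ev$provenance, "external")
})

test_that("PMI anti-symmetry maps the AUC to its complement", {
  co <- generate_cohort(default_psoriasis_config(seed = 14, n_cases = 20,
                                                 n_controls = 20))
  rel <- to_relative(collapse_to_rank(co$table, "genus"))
  idx <- define_index(features_fixture())
  flip <- features_fixture()
  flip$direction <- rev(flip$direction)
  a1 <- roc_curve(compute_pmi(rel, idx), co$metadata$group)$auc
  a2 <- roc_curve(compute_pmi(rel, define_index(flip)),
                  co$metadata$group)$auc
  expect_equal(a2, 1 - a1, tolerance = 1e-12)
})
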