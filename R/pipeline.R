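#' Pipeline configuration
#'
#' Bundles every stage parameter of the end-to-end analysis. Exactly one of
#' `input` (paths to an abundance TSV, metadata TSV and newick tree) or
#' `simulation` (a [synthetic_cohort_config()]) must be given.
#'
#' @param seed global seed; per-stage seeds are derived from it by stage
#'   name so stages can be rerun in isolation.
#' @param input list with elements `table`, `metadata`, `tree` (file paths).
#' @param simulation a `synthetic_cohort_config`.
#' @param output_dir directory for artifacts; `NULL` writes nothing.
#' @param filter_min_fraction low-confidence taxon filter threshold.
#' @param metric beta-diversity metric for [distance_matrix()].
#' @param n_permutations PERMANOVA permutations.
#' @param alpha,lda_threshold,n_boot LEfSe parameters.
#' @param k,reselect cross-validation parameters.
#' @param external optional independent cohort: a list of paths like
#'   `input`, or a `synthetic_cohort_config`; scored with the frozen index.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed, input = NULL, simulation = NULL,
                            output_dir = NULL, filter_min_fraction = 0.001,
                            metric = "weighted_unifrac",
                            n_permutations = 999, alpha = 0.05,
                            lda_threshold = 2.0, n_boot = 30L, k = 10L,
                            reselect = TRUE, external = NULL) {
  if (missing(seed)) stopf("seed is required")
  if (is.null(input) == is.null(simulation))
    stopf("exactly one of input paths or a simulation config must be given")
  if (!is.null(input) &&
      !all(c("table", "metadata", "tree") %in% names(input)))
    stopf("input must name table, metadata and tree paths")
  structure(list(seed = as.integer(seed), input = input,
                 simulation = simulation, output_dir = output_dir,
                 filter_min_fraction = filter_min_fraction, metric = metric,
                 n_permutations = n_permutations, alpha = alpha,
                 lda_threshold = lda_threshold, n_boot = as.integer(n_boot),
                 k = as.integer(k), reselect = reselect, external = external),
            class = "pipeline_config")
}

load_cohort <- function(spec_or_paths, seed) {
  if (inherits(spec_or_paths, "synthetic_cohort_config")) {
    co <- generate_cohort(spec_or_paths)
    co$tree <- generate_tree(taxon_ids(co$table),
                             seed = derive_seed(seed, "tree"))
    co
  } else {
    list(table = read_abundance_table(spec_or_paths$table),
         metadata = read_sample_metadata(spec_or_paths$metadata),
         tree = ape::read.tree(spec_or_paths$tree),
         truth = NULL)
  }
}

#' Run the end-to-end analysis pipeline
#'
#' Ingests (or simulates) a cohort, applies the low-confidence filter,
#' collapses to genus, computes alpha diversity (Chao1 at the cohort's
#' minimum depth, with a severity comparison among cases when both severity
#' strata are present), beta diversity (UniFrac distance matrix, PCoA,
#' PERMANOVA by case/control status), the Firmicutes:Bacteroidetes ratio,
#' LEfSe feature selection, PMI construction, ROC cutoff calibration,
#' stratified tenfold cross-validation, and — when an external cohort is
#' configured — frozen-index application. Identical config and seed give
#' identical outputs.
#'
#' @param cfg a `pipeline_config`.
#' @return list of class `pipeline_report` with each stage's result, the
#'   seed and a config hash; artifacts are written under
#'   `cfg$output_dir` when set.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  stage <- "ingest"
  report <- tryCatch({
    co <- load_cohort(cfg$simulation %||% cfg$input, cfg$seed)

    stage <- "filter"
    filt <- filter_low_confidence(co$table, cfg$filter_min_fraction)

    stage <- "collapse"
    genus <- collapse_to_rank(filt, "genus")
    rel <- to_relative(genus)

    stage <- "alpha_diversity"
    depth <- min(colSums(genus$counts))
    alpha_case_ctrl <- compare_alpha_diversity(
      genus, co$metadata$group[match(sample_ids(genus),
                                     co$metadata$sample_id)],
      depth = depth, seed = derive_seed(cfg$seed, "alpha"))
    sev <- co$metadata$severity[match(sample_ids(genus),
                                      co$metadata$sample_id)]
    alpha_severity <- NULL
    if (all(c("mild", "moderate_severe") %in% sev)) {
      sev[sev == "not_applicable"] <- NA
      alpha_severity <- compare_alpha_diversity(
        genus, sev, depth = depth, seed = derive_seed(cfg$seed, "alpha_sev"))
    }

    stage <- "beta_diversity"
    dm <- distance_matrix(filt, co$tree, cfg$metric)
    ord <- pcoa(dm)
    grp <- co$metadata$group[match(rownames(dm), co$metadata$sample_id)]
    adonis <- permanova(dm, grp, n_permutations = cfg$n_permutations,
                        seed = derive_seed(cfg$seed, "permanova"))

    stage <- "fb_ratio"
    fb <- fb_ratio(rel, co$metadata)

    stage <- "lefse"
    feats <- lefse(rel, co$metadata, alpha = cfg$alpha,
                   lda_threshold = cfg$lda_threshold, n_boot = cfg$n_boot,
                   seed = derive_seed(cfg$seed, "lefse"))

    stage <- "pmi_build"
    idx <- define_index(feats)
    scores <- compute_pmi(rel, idx)
    roc <- roc_curve(scores, grp)
    cut <- select_cutoff(roc)
    training <- apply_index(rel, idx, cut$cutoff, co$metadata,
                            provenance = "training")

    stage <- "cross_validation"
    cv <- cross_validate(rel, co$metadata, k = cfg$k,
                         seed = derive_seed(cfg$seed, "cv"),
                         reselect = cfg$reselect, idx = idx,
                         alpha = cfg$alpha, lda_threshold = cfg$lda_threshold,
                         n_boot = cfg$n_boot)

    external <- NULL
    if (!is.null(cfg$external)) {
      stage <- "external"
      ext <- load_cohort(cfg$external, derive_seed(cfg$seed, "external"))
      ext_rel <- to_relative(collapse_to_rank(
        filter_low_confidence(ext$table, cfg$filter_min_fraction), "genus"))
      external <- apply_index(ext_rel, idx, cut$cutoff, ext$metadata,
                              provenance = "external")
    }

    list(cohort = co, filtered = filt, genus_relative = rel,
         alpha = alpha_case_ctrl, alpha_severity = alpha_severity,
         distance = dm, ordination = ord, permanova = adonis,
         fb_ratio = fb, features = feats, index = idx, scores = scores,
         roc = roc, cutoff = cut, training = training, cv = cv,
         external = external)
  }, error = function(e)
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))

  report$seed <- cfg$seed
  report$config_hash <- config_hash(cfg)
  class(report) <- "pipeline_report"
  if (!is.null(cfg$output_dir)) write_artifacts(report, cfg)
  report
}

config_hash <- function(cfg) {
  # hash only the analysis-relevant fields, not artifact paths
  core <- unclass(cfg)
  core$output_dir <- NULL
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  writeLines(paste(deparse(core), collapse = "\n"), tmp)
  unname(tools::md5sum(tmp))
}

write_artifacts <- function(report, cfg) {
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(cfg$output_dir, f)
  stamp <- sprintf("# seed=%d config_hash=%s", report$seed,
                   report$config_hash)
  write_tsv <- function(df, f) {
    con <- file(p(f), "w")
    on.exit(close(con))
    writeLines(stamp, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_abundance_table(report$filtered, p("filtered_counts.tsv"))
  write_sample_metadata(report$cohort$metadata, p("metadata.tsv"))
  if (!is.null(report$cohort$tree))
    ape::write.tree(report$cohort$tree, p("tree.nwk"))
  dm <- as.matrix(report$distance)
  write_tsv(data.frame(sample_id = rownames(dm), dm, check.names = FALSE),
            "distance_matrix.tsv")
  write_tsv(report$features, "differential_features.tsv")
  write_index(report$index, p("index.json"))
  write_tsv(data.frame(threshold = report$roc$thresholds,
                       sensitivity = report$roc$sensitivity,
                       specificity = report$roc$specificity),
            "roc_training.tsv")
  write_tsv(data.frame(threshold = report$cv$roc$thresholds,
                       sensitivity = report$cv$roc$sensitivity,
                       specificity = report$cv$roc$specificity),
            "roc_cv.tsv")
  summary_lines <- c(stamp, utils::capture.output(print(report)))
  writeLines(summary_lines, p("report.txt"))
  invisible(cfg$output_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report (seed", x$seed, ", config", x$config_hash, ")\n")
  cat(sprintf("  samples: %d  genera: %d\n", ncol(x$genus_relative$counts),
              nrow(x$genus_relative$counts)))
  cat(sprintf("  alpha (case vs control) p = %.4g\n", x$alpha$p_value))
  if (!is.null(x$alpha_severity))
    cat(sprintf("  alpha (mild vs moderate-severe) p = %.4g\n",
                x$alpha_severity$p_value))
  cat(sprintf("  PERMANOVA pseudo-F = %.3f, p = %.4g\n",
              x$permanova$pseudo_F, x$permanova$p_value))
  cat(sprintf("  F:B ratio p = %.4g\n", x$fb_ratio$p_value))
  cat(sprintf("  discriminant genera: %s\n",
              paste(x$features$genus, collapse = ", ")))
  cat(sprintf("  training AUC = %.3f; cutoff %.3f (sens %.2f, spec %.2f)\n",
              x$roc$auc, x$cutoff$cutoff, x$cutoff$sensitivity,
              x$cutoff$specificity))
  cat(sprintf("  tenfold CV held-out AUC = %.3f\n", x$cv$roc$auc))
  if (!is.null(x$external))
    cat(sprintf("  external AUC = %.3f (sens %.2f, spec %.2f)\n",
                x$external$auc, x$external$sensitivity,
                x$external$specificity))
  invisible(x)
}
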