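#' Synthetic two-group cohort configuration
#'
#' Defines a Dirichlet-multinomial generative model for a case/control 16S
#' cohort at genus level: per-sample genus proportions are drawn from a
#' Dirichlet whose mean is the control baseline (cases: baseline times the
#' effect multipliers, renormalized) and whose precision is `concentration`;
#' sequencing depth is lognormal; counts are multinomial at that depth.
#'
#' @param n_cases,n_controls number of samples per group (>= 2).
#' @param baseline named numeric vector of mean control-group genus
#'   proportions; must sum to 1.
#' @param lineages named character vector of lineage strings for the baseline
#'   genera.
#' @param effect_multipliers named numeric vector of fold-changes applied to
#'   the Dirichlet mean in cases; genera not named get 1. All values > 0.
#' @param concentration Dirichlet precision (> 0); smaller values give more
#'   sample-to-sample overdispersion.
#' @param depth_mean,depth_sd mean and standard deviation of per-sample read
#'   depth (the lognormal is parameterized from these moments).
#' @param seed integer seed making the cohort reproducible.
#' @return A `synthetic_cohort_config` list.
#' @export
synthetic_cohort_config <- function(n_cases, n_controls, baseline, lineages,
                                    effect_multipliers = numeric(),
                                    concentration = 50,
                                    depth_mean = 29872.93,
                                    depth_sd = 6452.75,
                                    seed = 1L) {
  if (!is.numeric(n_cases) || n_cases < 2) stopf("invalid field n_cases")
  if (!is.numeric(n_controls) || n_controls < 2) stopf("invalid field n_controls")
  if (is.null(names(baseline)) || anyDuplicated(names(baseline)))
    stopf("invalid field baseline: must be uniquely named")
  if (abs(sum(baseline) - 1) > 1e-8)
    stopf("invalid field baseline: proportions must sum to 1")
  if (any(baseline <= 0)) stopf("invalid field baseline: values must be > 0")
  missing <- setdiff(names(baseline), names(lineages))
  if (length(missing))
    stopf("invalid field lineages: no lineage for %s",
          paste(missing, collapse = ", "))
  mult <- stats::setNames(rep(1, length(baseline)), names(baseline))
  if (length(effect_multipliers)) {
    unknown <- setdiff(names(effect_multipliers), names(baseline))
    if (length(unknown))
      stopf("invalid field effect_multipliers: unknown genus %s",
            paste(unknown, collapse = ", "))
    if (any(effect_multipliers <= 0))
      stopf("invalid field effect_multipliers: values must be > 0")
    mult[names(effect_multipliers)] <- effect_multipliers
  }
  if (!is.numeric(concentration) || concentration <= 0)
    stopf("invalid field concentration")
  if (!is.numeric(depth_mean) || depth_mean <= 0) stopf("invalid field depth_mean")
  if (!is.numeric(depth_sd) || depth_sd <= 0) stopf("invalid field depth_sd")
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 baseline = baseline,
                 lineages = lineages[names(baseline)],
                 effect_multipliers = mult,
                 concentration = concentration,
                 depth_mean = depth_mean, depth_sd = depth_sd,
                 seed = as.integer(seed)),
            class = "synthetic_cohort_config")
}

#' Expected group-level genus proportions of a config
#'
#' The Dirichlet mean for one group: the baseline, multiplied by the effect
#' multipliers for cases, renormalized.
#'
#' @param cfg a `synthetic_cohort_config`.
#' @param group `"case"` or `"control"`.
#' @return named numeric vector summing to 1.
#' @export
expected_proportions <- function(cfg, group = c("control", "case")) {
  group <- match.arg(group)
  p <- cfg$baseline
  if (group == "case") p <- p * cfg$effect_multipliers
  p / sum(p)
}

# Control-group genus baseline emulating a psoriasis 16S study: phylum sums
# Bacteroidetes 59.9%, Firmicutes 33.0%, Proteobacteria 4.2%,
# Actinobacteria 0.8%, Verrucomicrobia 1.4%, Fusobacteria 0.7%.
psoriasis_baseline <- function() {
  c(Bacteroides = 0.1400, Prevotella = 0.1873, Paraprevotella = 0.0517,
    Alistipes = 0.0900, Parabacteroides = 0.0700, Odoribacter = 0.0300,
    Butyricimonas = 0.0300,
    Faecalibacterium = 0.0550, Blautia = 0.0305, Roseburia = 0.0500,
    Ruminococcus = 0.0500, Oscillospira = 0.0400, Coprococcus = 0.0300,
    Dorea = 0.0250, Lachnospira = 0.0200, Streptococcus = 0.0150,
    Clostridium = 0.0145,
    Escherichia = 0.0220, Sutterella = 0.0200,
    Bifidobacterium = 0.0080, Akkermansia = 0.0140, Fusobacterium = 0.0070)
}

psoriasis_lineages <- function() {
  bact <- "k__Bacteria; p__Bacteroidetes; c__Bacteroidia; o__Bacteroidales; f__%s; g__%s"
  clos <- "k__Bacteria; p__Firmicutes; c__Clostridia; o__Clostridiales; f__%s; g__%s"
  c(Bacteroides = sprintf(bact, "Bacteroidaceae", "Bacteroides"),
    Prevotella = sprintf(bact, "Prevotellaceae", "Prevotella"),
    Paraprevotella = sprintf(bact, "Paraprevotellaceae", "Paraprevotella"),
    Alistipes = sprintf(bact, "Rikenellaceae", "Alistipes"),
    Parabacteroides = sprintf(bact, "Porphyromonadaceae", "Parabacteroides"),
    Odoribacter = sprintf(bact, "Odoribacteraceae", "Odoribacter"),
    Butyricimonas = sprintf(bact, "Odoribacteraceae", "Butyricimonas"),
    Faecalibacterium = sprintf(clos, "Ruminococcaceae", "Faecalibacterium"),
    Blautia = sprintf(clos, "Lachnospiraceae", "Blautia"),
    Roseburia = sprintf(clos, "Lachnospiraceae", "Roseburia"),
    Ruminococcus = sprintf(clos, "Ruminococcaceae", "Ruminococcus"),
    Oscillospira = sprintf(clos, "Ruminococcaceae", "Oscillospira"),
    Coprococcus = sprintf(clos, "Lachnospiraceae", "Coprococcus"),
    Dorea = sprintf(clos, "Lachnospiraceae", "Dorea"),
    Lachnospira = sprintf(clos, "Lachnospiraceae", "Lachnospira"),
    Streptococcus = "k__Bacteria; p__Firmicutes; c__Bacilli; o__Lactobacillales; f__Streptococcaceae; g__Streptococcus",
    Clostridium = sprintf(clos, "Clostridiaceae", "Clostridium"),
    Escherichia = "k__Bacteria; p__Proteobacteria; c__Gammaproteobacteria; o__Enterobacteriales; f__Enterobacteriaceae; g__Escherichia",
    Sutterella = "k__Bacteria; p__Proteobacteria; c__Betaproteobacteria; o__Burkholderiales; f__Alcaligenaceae; g__Sutterella",
    Bifidobacterium = "k__Bacteria; p__Actinobacteria; c__Actinobacteria; o__Bifidobacteriales; f__Bifidobacteriaceae; g__Bifidobacterium",
    Akkermansia = "k__Bacteria; p__Verrucomicrobia; c__Verrucomicrobiae; o__Verrucomicrobiales; f__Verrucomicrobiaceae; g__Akkermansia",
    Fusobacterium = "k__Bacteria; p__Fusobacteria; c__Fusobacteriia; o__Fusobacteriales; f__Fusobacteriaceae; g__Fusobacterium")
}

#' Default psoriasis-like cohort configuration
#'
#' A 22-genus baseline across Bacteroidetes, Firmicutes, Proteobacteria,
#' Actinobacteria, Verrucomicrobia and Fusobacteria whose control-group
#' phylum sums are (59.9, 33.0, 4.2, 0.8, 1.4, 0.7)%. Cases carry a x2.5
#' enrichment of Faecalibacterium and Blautia, a x0.4 depletion of
#' Bacteroides and Paraprevotella, and a x0.05 depletion of Akkermansia
#' (Verrucomicrobia effectively absent in cases). The baseline masses of the
#' affected genera are balanced so the case renormalization factor is ~1 and
#' the case-group Dirichlet-mean Firmicutes:Bacteroidetes ratio is ~0.95.
#' Depth is lognormal with mean 29,873 and sd 6,453 reads.
#'
#' @param seed integer seed.
#' @param n_cases,n_controls samples per group.
#' @return A `synthetic_cohort_config`.
#' @export
default_psoriasis_config <- function(seed = 1L, n_cases = 50L, n_controls = 50L) {
  synthetic_cohort_config(
    n_cases = n_cases, n_controls = n_controls,
    baseline = psoriasis_baseline(),
    lineages = psoriasis_lineages(),
    effect_multipliers = c(Faecalibacterium = 2.5, Blautia = 2.5,
                           Bacteroides = 0.4, Paraprevotella = 0.4,
                           Akkermansia = 0.05),
    concentration = 50, depth_mean = 29872.93, depth_sd = 6452.75,
    seed = seed)
}

#' Generate a synthetic cohort
#'
#' Draws a complete two-group cohort from a config: per-sample Dirichlet
#' genus proportions, lognormal depths, multinomial counts; plus metadata
#' and the injected ground-truth genus sets.
#'
#' @param cfg a `synthetic_cohort_config`.
#' @return A list with `table` (an `abundance_table` of counts), `metadata`
#'   (a `sample_metadata` data.frame) and `truth` (list with
#'   `increased_genera` and `decreased_genera`: the genus sets injected as
#'   case-enriched / case-depleted).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_cohort_config"))
  local_seed(cfg$seed, {
    genera <- names(cfg$baseline)
    n <- cfg$n_cases + cfg$n_controls
    group <- rep(c("case", "control"), c(cfg$n_cases, cfg$n_controls))
    ids <- c(sprintf("case_%03d", seq_len(cfg$n_cases)),
             sprintf("control_%03d", seq_len(cfg$n_controls)))
    mean_case <- expected_proportions(cfg, "case")
    mean_ctrl <- expected_proportions(cfg, "control")
    lsd <- sqrt(log(1 + (cfg$depth_sd / cfg$depth_mean)^2))
    lmu <- log(cfg$depth_mean) - lsd^2 / 2
    counts <- matrix(0, length(genera), n, dimnames = list(genera, ids))
    for (i in seq_len(n)) {
      mu <- if (group[i] == "case") mean_case else mean_ctrl
      g <- stats::rgamma(length(genera), shape = mu * cfg$concentration)
      p <- g / sum(g)
      depth <- max(1, round(stats::rlnorm(1, lmu, lsd)))
      counts[, i] <- stats::rmultinom(1, depth, p)
    }
    severity <- ifelse(group == "control", "not_applicable",
                       rep_len(c("mild", "moderate_severe"), cfg$n_cases))
    md <- sample_metadata(data.frame(
      sample_id = ids, group = group, severity = severity,
      age = round(stats::rnorm(n, 48, 12)),
      sex = sample(c("F", "M"), n, replace = TRUE),
      bmi = round(stats::rnorm(n, 26, 3), 1),
      stringsAsFactors = FALSE))
    mult <- cfg$effect_multipliers
    list(table = abundance_table(counts, cfg$lineages, "counts"),
         metadata = md,
         truth = list(increased_genera = sort(names(mult)[mult > 1]),
                      decreased_genera = sort(names(mult)[mult < 1])))
  })
}

#' Generate a random rooted phylogeny over a set of taxa
#'
#' Random sequential joins produce a bifurcating rooted topology; branch
#' lengths are exponential. Used as a substrate for UniFrac when no real
#' 16S tree is available.
#'
#' @param taxon_ids leaf labels (at least 2).
#' @param seed integer seed.
#' @param mean_branch_length mean of the exponential branch lengths.
#' @return An `ape::phylo` rooted binary tree with `length(taxon_ids)` leaves.
#' @export
generate_tree <- function(taxon_ids, seed = 1L, mean_branch_length = 0.1) {
  if (length(taxon_ids) < 2L) stopf("need at least 2 taxa to build a tree")
  local_seed(seed, {
    nodes <- as.list(taxon_ids)
    bl <- function() stats::rexp(1, rate = 1 / mean_branch_length)
    while (length(nodes) > 1L) {
      i <- sample.int(length(nodes), 2L)
      joined <- sprintf("(%s:%.8f,%s:%.8f)",
                        nodes[[i[1]]], bl(), nodes[[i[2]]], bl())
      nodes[[i[1]]] <- joined
      nodes[[i[2]]] <- NULL
    }
    ape::read.tree(text = paste0(nodes[[1]], ";"))
  })
}
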