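---
title: "Methods and design of pmindex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of pmindex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and data model

`pmindex` analyses genus-level 16S gut-microbiome case/control cohorts. The
central object is the `abundance_table`: a non-negative taxon × sample
matrix flagged as either raw counts or proportions, with a Greengenes-style
lineage per taxon. Taxa are rows, samples are columns, and every operation
either conserves per-sample totals exactly (rank collapse) or re-flags the
table explicitly (`to_relative()`). Sample metadata carries case/control
status and a psoriasis severity stratum (`mild` / `moderate_severe` for
cases, `not_applicable` for controls), and trees are `ape::phylo` objects
read and written as newick.

Two taxonomy dialects are accepted on input — prefixed
(`k__Bacteria; p__Firmicutes; ...`) and bare positional — and the prefixed
form is always emitted. Ranks absent from a lineage stay as explicit empty
strings. When a table is collapsed to a rank, taxa with an empty value at
that rank are pooled under `unclassified_<parent rank>_<parent name>` rather
than into one global bin, so that a genus set used by an index can never
silently absorb unrelated unclassified reads.

The low-confidence filter drops every taxon whose total count across the
cohort is *strictly below* a fraction (default 0.1%) of the grand total; a
taxon sitting exactly at the threshold is kept. The filter is applied at the
input (OTU) level before rank collapse in `run_pipeline()`, mirroring the
usual position of this step in 16S workflows; both the threshold and the
position are plain function arguments, so the alternative order is a
two-line change for a user who needs it.

# The synthetic cohort generator

No raw sequencing data ships with the package; instead `generate_cohort()`
draws complete cohorts from an explicit generative model so that every
downstream claim is testable against a known ground truth.

The model is Dirichlet-multinomial. Each group has a mean genus composition:
controls use the configured baseline, cases use the baseline multiplied by
per-genus effect fold-changes and renormalized. A sample's proportions are
drawn from a Dirichlet with that mean and precision `concentration`; its
read depth from a lognormal parameterized by a target mean and standard
deviation (default 29,873 ± 6,453 reads, matching typical post-QC mapped
read counts for this study design); its counts from a multinomial at that
depth. Everything is deterministic given the config's seed.

The default psoriasis-like configuration uses 22 genera whose control-group
phylum sums are Bacteroidetes 59.9%, Firmicutes 33.0%, Proteobacteria 4.2%,
Actinobacteria 0.8%, Verrucomicrobia 1.4% and Fusobacteria 0.7%. Cases
carry ×2.5 enrichment of *Faecalibacterium* and *Blautia*, ×0.4 depletion
of *Bacteroides* and *Paraprevotella*, and ×0.05 depletion of *Akkermansia*
(modelling the near-absence of Verrucomicrobia in cases without a
degenerate Dirichlet mean). Three deliberate choices:

- **Balanced effects.** The baseline masses of the perturbed genera were
  chosen so that the total perturbed mass gained by cases
  (≈ 1.5 × 8.55%) equals the mass lost (≈ 0.6 × 19.17% + 0.95 × 1.4%).
  The case renormalization factor is then ≈ 1 and the seventeen unperturbed
  genera have *no* compositional fold-change between groups. Without this
  balance, renormalization would give every null genus a spurious ~15%
  relative shift — easily detectable at n = 50 per group — and "recovering
  exactly the injected genera" would be unachievable for any method working
  on relative abundances. With it, the null genera are exact nulls and the
  false-positive rate of downstream selection is governed purely by the
  test level.
- **Composition targets.** The balance constraint plus the fixed ×2.5/×0.4
  effects pin the case-group Dirichlet-mean Firmicutes:Bacteroidetes ratio
  at ≈ 0.95 (44.6/47.1); the individual case phylum fractions come out
  ≈ 48.4% / 45.8% rather than exactly 47.1% / 44.6%, because matching the
  fractions, the fold-changes and the near-constant remaining phyla
  simultaneously is overdetermined. The ratio was prioritised since it is
  the quantity the downstream F:B analysis consumes.
- **Concentration 50.** The Dirichlet precision controls sample-to-sample
  overdispersion. 50 is a realistic value for stool 16S genus profiles
  (per-genus CVs of roughly 15–60%) and produces per-sample F:B ratios
  dispersed around the group means (cases above controls). The generator
  does not attempt to match any particular published within-group SD of the
  ratio; with a single precision parameter for all genera that extra degree
  of freedom does not exist.

Random test phylogenies come from `generate_tree()`: random sequential
joins give a rooted bifurcating topology with exponential branch lengths
(mean 0.1). Tree shape only needs to be a plausible substrate for UniFrac;
no evolutionary realism is claimed.

What the simulator does **not** emulate: OTU-level noise below the genus
rank, taxonomic mis-assignment, depth–composition correlation, zero
inflation beyond what the Dirichlet-multinomial induces, and covariate
structure (age/sex/BMI are drawn independently of group). Tests passing on
these cohorts therefore demonstrate correctness of the algorithms under the
stated model, not robustness to every artefact of real amplicon data.

# Diversity

*Chao1* is the bias-corrected form `S_obs + F1(F1−1)/(2(F2+1))`, defined
for any sample with at least one read and never below observed richness.
Group comparisons of alpha diversity compute Chao1 on counts rarefied
(without replacement) to a common depth — by default the cohort minimum —
and compare groups with a two-sided Mann–Whitney U test; a Welch t-test is
available by argument since the choice is a convention, not a derivation.

*UniFrac* is implemented by a single per-edge accumulation: for each edge
of the rooted tree, the fraction of each community descending through it.
Unweighted UniFrac is the branch length unique to one community over the
branch length covered by either; weighted UniFrac is
`sum(len × |A − B|)`, optionally divided by its tree-wise maximum
`sum(len × (A + B))`. The non-normalized variant is the default, matching
the long-standing default of the QIIME-era implementation. The matrix
routine `distance_matrix()` vectorises the same edge accumulation (it is
tested to agree exactly with the pairwise calls) so that hundreds of
cohort-sized matrices can be computed for calibration studies.

*PCoA* is classical scaling of the Gower-centred `−D²/2` matrix; axes with
positive eigenvalues carry coordinates, negative eigenvalues are reported
but excluded from the proportion-explained denominator.

*PERMANOVA* uses the one-factor pseudo-F partition of squared distances
(Anderson 2001) with label permutations and the add-one p-value
`(1 + #{F* ≥ F}) / (1 + n_permutations)`, so p can never be zero and its
floor is `1/(n_permutations+1)`. 999 permutations by default.

# Differential abundance

`lefse()` follows the two-class LDA-effect-size recipe: per-genus
Kruskal–Wallis at `alpha = 0.05` on per-million-scaled relative abundances
(the rescaling makes the procedure invariant to arbitrary per-sample
scaling of its input), then, for the survivors, 30 rounds of a
one-component `MASS::lda` on 2/3 class-stratified subsamples. A genus's
per-round effect size averages the magnitude of its raw class-mean
difference with its share (|unit-coefficient| × axis separation) of the
class-mean difference along the discriminant axis; the reported score is
`log10(1 + mean effect)` and genera below the score threshold (default 2.0)
are dropped. Direction is the sign of the case-minus-control mean.
Columns that are constant within classes in a subsample are jittered
(σ = 10⁻⁵ on the per-million scale) to keep the discriminant well-posed.
The subclass (within-class Wilcoxon) stage of the original procedure is a
structural no-op in a two-plain-class design and is not exposed.

Numeric parity with any particular external LEfSe build is *not* a design
goal; the procedure's test surface is ground-truth recovery on simulated
cohorts, false-positive calibration on null cohorts, monotonicity of the
score in the injected fold-change, and scale invariance.

Because the screen runs at level alpha per genus with no multiplicity
correction (as in the original tool), a cohort with ~17 truly null genera
reports on average ~0.9 spurious genera alongside the true ones, and the
probability that a *single* cohort yields exactly the injected sets is only
about 0.42. Recovery is therefore assessed **seed-averaged**: the selected
sets are aggregated over 10 independent cohorts by majority vote. True
effects appear in essentially every cohort; any given false positive
appears in ~5% of them, so the majority-vote sets equal the injected truth
with overwhelming probability. This is the package's acceptance notion of
"exact recovery" and the reason a single pipeline run may show one or two
borderline extra genera (Bonferroni correction, by contrast, is applied to
the phylum-level comparisons, where it is conventional).

`fb_ratio()` sums Firmicutes and Bacteroidetes abundances per sample and
compares per-sample ratios between groups with a two-sided Mann–Whitney U
test (Welch t by argument). A pseudocount of half the smallest nonzero
phylum sum is used only where a term is zero, keeping every ratio finite
and positive.

# The PMI

`define_index()` freezes the discriminant genera into an
`index_definition`: case-enriched genera form the numerator, control-
enriched the denominator (both non-empty, disjoint). `compute_pmi()` scores
a genus-level relative table as `log10(Σ numerator / Σ denominator)`.
Choices that were genuinely open:

- **Log base 10**, matching the scale of LDA scores and giving cutoffs in
  readable decades; configurable.
- **Relative abundances** (not rarefied counts) before summing: the index
  is then depth-independent, which cross-cohort transfer requires.
- **Pseudocount** `half_min_nonzero`: half the smallest nonzero proportion
  of the scored table, applied to both sums only for samples where either
  sum is zero. A fixed ε is available when cross-study comparability of the
  padding itself matters.
- Genera named by the index but absent from a table contribute zero and
  raise a warning rather than an error, since harmonized external cohorts
  routinely lack a genus.

`roc_curve()` evaluates thresholds at midpoints between consecutive
distinct scores plus ±∞ sentinels, calling a sample a case when
`score ≥ threshold`. The trapezoidal AUC equals the tie-aware concordance
probability P(score_case > score_control) + ½P(tie) and is invariant under
strictly increasing score transforms. `select_cutoff()` picks the threshold
where sensitivity and specificity intersect — minimal |sens − spec|, ties
broken by larger sens + spec, then by the smaller threshold; sentinels are
never returned, so the cutoff always lies within the observed score range.

`cross_validate()` uses stratified k-fold assignment (class proportions per
fold within one sample of proportional). By default the discriminant genera
are **re-selected inside every training split** and the held-out fold is
scored with that fold-specific index, so the pooled held-out ROC carries no
feature-selection leakage; `reselect = FALSE` evaluates a fixed index
instead, and with deterministic scores its pooled AUC provably equals the
full-data AUC (a consistency check in the tests). `apply_index()` carries a
frozen index and cutoff to an external cohort and reports sensitivity,
specificity and the cohort's own AUC.

# Reproducibility and problem sizes

Every stochastic routine takes an explicit seed and restores the caller's
RNG state. `run_pipeline()` fans a single global seed out to per-stage
seeds derived from stage names, so any stage can be re-run in isolation;
identical config + seed yields byte-identical artifacts, each stamped with
the config hash.

The test suite works at sizes chosen to make the statistical properties it
asserts sharp while keeping a full run interactive: oracle equivalence on
200 random trees of up to 10 leaves and exhaustive AUC concordance up to
n = 8; type-I calibration of PERMANOVA over 500 null cohorts of 50 + 50
samples (199 permutations each) and of the LEfSe screen over 20 null
cohorts; parameter recovery over 10 seeds of the default 50 + 50 cohort
with tenfold leakage-free cross-validation. The acceptance script simulates
a 55 + 27 training cohort and an independent 19 + 20 validation cohort —
the sample sizes of the study design this pipeline targets.

# Known limitations

- UniFrac is the plain per-edge formulation; no bit-parallel or
  generalized variants.
- PERMANOVA is one-factor only; covariate adjustment (age, sex, BMI) is out
  of scope even though the metadata carries covariates.
- LEfSe here is two-class, genus-rank only; multi-rank and
  subclass-structured designs are not implemented.
- The simulator's single concentration parameter cannot reproduce
  genus-specific overdispersion or the exact within-group SDs of derived
  statistics.
- Synthetic cohorts are far cleaner than real amplicon data; discrimination
  metrics obtained on them (AUCs ≈ 0.95+) characterise the pipeline under
  its own model, not expected clinical performance.
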