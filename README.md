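# pmindex

Gut-microbiome dysbiosis analysis for case/control 16S cohorts, built around
the **Psoriasis-Microbiome Index (PMI)** — a per-sample log-ratio score that
summarises psoriasis-associated shifts in the genus-level gut community and
can be carried, with a frozen cutoff, to independent cohorts.

The package is aimed at microbiome researchers who work with genus-collapsed
OTU tables (Greengenes-style lineages) and want a single tested pipeline for:

- abundance-table handling: TSV I/O, taxonomy parsing, the 0.1%
  low-confidence taxon filter, rank collapse, relative abundances;
- alpha diversity (bias-corrected Chao1 on rarefied counts) and
  phylogenetic beta diversity (unweighted and weighted UniFrac), with PCoA
  and PERMANOVA (ADONIS) permutation tests;
- LEfSe-style differential genus selection: a Kruskal–Wallis screen followed
  by bootstrapped linear-discriminant effect sizes on a log10 scale;
- the Firmicutes:Bacteroidetes ratio with a group comparison test;
- the PMI itself: index construction from discriminant genera, ROC cutoff
  calibration, stratified tenfold cross-validation, and application of a
  frozen index to an external cohort;
- a Dirichlet-multinomial cohort simulator that generates realistic
  psoriasis-like study data (including injected ground-truth effects) so
  every stage is testable without access to raw sequencing archives.

## The index

For a sample with genus-level relative abundances, given a set *I* of genera
increased in cases and a set *D* of genera decreased in cases,

```
PMI = log10( sum_{g in I} p_g  /  sum_{g in D} p_g )
```

with a pseudocount (half the smallest nonzero proportion) applied only when
a sum is zero. Samples score high when the case-enriched genera dominate the
case-depleted ones; classification calls a sample a case when its score is
at or above a cutoff chosen where the sensitivity and specificity curves of
the training ROC intersect. In the psoriasis setting the discriminant sets
are typically *I* = {Faecalibacterium, Blautia} and
*D* ⊇ {Bacteroides, Paraprevotella}.

## Worked example

```r
library(pmindex)

cfg <- default_psoriasis_config(seed = 42, n_cases = 55, n_controls = 27)
rep <- run_pipeline(pipeline_config(
  seed = 42, simulation = cfg,
  external = default_psoriasis_config(seed = 4242, n_cases = 19, n_controls = 20)))
print(rep)
```

```
Pipeline report (seed 42 , config 13ea4e69beb593e8dbe6d4096bcc2dd0 )
  samples: 82  genera: 22
  alpha (case vs control) p = 2.439e-06
  alpha (mild vs moderate-severe) p = 0.7932
  PERMANOVA pseudo-F = 14.896, p = 0.001
  F:B ratio p = 2.884e-07
  discriminant genera: Bacteroides, Faecalibacterium, Paraprevotella, Akkermansia, Blautia, Coprococcus
  training AUC = 0.991; cutoff -0.110 (sens 0.96, spec 0.96)
  tenfold CV held-out AUC = 0.947
  external AUC = 0.979 (sens 0.95, spec 0.95)
```

Reading the report: the simulated cohort of 55 cases and 27 controls shows a
community-level case/control difference (weighted-UniFrac PERMANOVA
pseudo-F = 14.9 at the permutation floor p = 0.001), an elevated
Firmicutes:Bacteroidetes ratio in cases (0.91 ± 0.32 vs 0.58 ± 0.17,
Mann–Whitney p = 2.9e-07), and LEfSe recovers the genera the simulator
actually perturbed (Faecalibacterium and Blautia up in cases; Bacteroides,
Paraprevotella and Akkermansia down; Coprococcus here is a borderline
Kruskal–Wallis pick at alpha = 0.05). The PMI built from those genera
separates the groups with a training AUC of 0.99, holds up under
leakage-free tenfold cross-validation (held-out AUC 0.95), and the frozen
index + cutoff transfers to an independent 19 + 20 cohort (AUC 0.98,
sensitivity/specificity 0.95/0.95).

Individual stages are available as plain functions (`chao1()`, `rarefy()`,
`unweighted_unifrac()`, `weighted_unifrac()`, `distance_matrix()`, `pcoa()`,
`permanova()`, `lefse()`, `fb_ratio()`, `define_index()`, `compute_pmi()`,
`roc_curve()`, `select_cutoff()`, `cross_validate()`, `apply_index()`), and
the simulator via `default_psoriasis_config()` / `generate_cohort()` /
`generate_tree()`. See `vignettes/pmindex-methods.Rmd` for the modelling
details and design choices.

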