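# metabostrat

Stratification of bulk tumor cohorts by metabolic gene expression, as a
tested, reusable R pipeline.

## The scientific problem

Tumor cohorts can be split into patient clusters by the expression of
nuclear-encoded oxidative phosphorylation (OXPHOS) and glycolysis genes, and
those clusters can differ sharply in overall survival. The signature of
interest is a **threshold effect**: the cluster with the highest OXPHOS
expression survives best, while the adjacent cluster with the second-highest
expression can do worst — survival is not monotone in expression. Before
such a finding can be believed, pedestrian explanations must be excluded:
skeletal-muscle contamination of specimens, hypoxia, and infiltrating
cytotoxic T-cells whose own metabolic expression could mimic tumor-intrinsic
upregulation.

`metabostrat` implements the full analysis for researchers working with
normalized (RSEM-like, linear-scale) expression cohorts:

* **Resampling consensus clustering** (Monti-style; hierarchical base
  learner, Euclidean distance, average linkage, 250 × 80% subsamples) of
  samples and genes, with cluster-number selection by **NED** — the root
  mean square distance between the consensus matrix *M* and the
  "theoretically perfect" matrix *P* of a partition:

  $$\mathrm{NED}(M, L) = \sqrt{\tfrac{1}{n(n-1)/2}\textstyle\sum_{i<j}(M_{ij}-P_{ij})^2},
  \qquad P_{ij} = \mathbf 1[L_i = L_j].$$

  NED = 0 is perfect reproducibility; 0.5 is a maximally uninformative
  consensus. `select_optimal_k()` reports the finest perfectly-reproducible
  partition, falling back to the strict NED minimum on noisy data, and
  flags cohorts without reproducible structure.
* **ssGSEA** scoring (rank-weighted ECDF statistic, `alpha = 0.75`) of
  muscle, hypoxia and immune-subset signatures on linear expression, with
  per-cohort Z-scores and subtractive combined scores such as
  z(cytotoxic) − z(Treg).
* **Survival stratification**: Kaplan–Meier curves, median survival
  (smallest event time with S(t) ≤ 0.5), pairwise and pooled log-rank
  (Mantel–Cox) comparisons against a reference cluster.
* **Group statistics**: per-gene Welch t-tests (BH, FDR 0.05),
  geometric-mean fold annotation at 1.4-fold, chi-square mutation–cluster
  association on impactful mutations (SIFT deleterious OR PolyPhen
  probably/possibly damaging; BH, FDR 0.01), covariate-by-cluster reports
  (ANOVA + Tukey HSD + Spearman trend), and a genome-wide Pearson screen
  against a metabolic ssGSEA score.
* **A T-cell contamination mixture model**: expected fold changes under an
  assumed cytotoxic T-cell fraction *f*,
  FC(g) = (f·μ_tcell + (1−f)·μ_tumor + 1)/(μ_tumor + 1), compared with
  observed geometric-mean fold changes and classified per gene as
  *potentially explainable* by contamination or *not explainable*.
* **A synthetic cohort generator** with complete ground truth (planted
  expression clusters, non-monotone hazards, immune gradients,
  muscle-contaminated samples, mtDNA trends, annotated mutations,
  per-cell-type profiles), so the whole pipeline is testable end to end.

## Worked example

```r
library(metabostrat)

cohort <- generate_cohort(cohort_config(master_seed = 42))
sig <- c(cohort$gene_sets$oxphos$genes, cohort$gene_sets$glycolysis$genes)
tumors <- cohort$expression$values[, names(cohort$truth_labels)]

tw <- two_way_cluster(tumors, sample_k_range = 2:8, gene_k_range = 2:4,
                      genes = sig, signature_genes = cohort$gene_sets$oxphos$genes,
                      n_resamples = 250, seed = 1)
tw$sample_result
#> consensus clustering over k = 2..8
#> chosen k = 4 (NED = 0.0000)
```

The per-k NED trace shows the perfect plateau up to the planted k = 4 and
the jump once real clusters must be split:

```r
tw$sample_result$ned_table
#>   k        ned
#> 1 2 0.00000000
#> 2 3 0.00000000
#> 3 4 0.00000000
#> 4 5 0.01573388
#> 5 6 0.01639508
#> 6 7 0.03539740
#> 7 8 0.04590930
```

Survival stratification reproduces the threshold effect (cluster 1 =
highest OXPHOS, best survival; cluster 2 = second-highest expression, worst
survival):

```r
cluster_survival_report(cohort$clinical, tw$sample_labels, reference_cluster = 1)
#> cluster survival report
#>  cluster  n events median_survival
#>        1 50     21       117.11933
#>        2 50     46        17.58964
#>        3 50     34        72.43726
#>        4 50     34        83.11023
#> pairwise log-rank vs cluster 1:
#>  cluster vs chi_square df            p         p_bh
#>        2  1  40.824119  1 1.665646e-10 4.996938e-10
#>        3  1   8.480298  1 3.590132e-03 5.385198e-03
#>        4  1   3.956970  1 4.667766e-02 4.667766e-02
```

Median survival is in months; cluster 1's 117 months versus cluster 2's
17.6 months is the planted hazard contrast (0.005 vs 0.03 month⁻¹), and the
pairwise Mantel–Cox tests compare each cluster to cluster 1.

The immune balance declines across clusters, and the mixture model rejects
T-cell contamination as an explanation for the planted (tumor-intrinsic)
expression differences:

```r
scores <- ssgsea_table(tumors, cohort$gene_sets)
round(tapply(combined_subtractive_score(scores, "cytotoxic", "treg"),
             tw$sample_labels, mean), 2)
#>     1     2     3     4
#>  2.08  0.59 -0.58 -2.09

mixture_report(tumors[sig, ], tw$sample_labels, cohort$cell_profiles, f = 0.5)
#> mixture model at f = 0.50: 100 genes, 100 (100.0%) not explainable by contamination
```

A thin command-line front end (`inst/cli/metabostrat.R`) exposes
`simulate`, `cluster`, `score`, `survival`, `de`, `assoc`, `correlate`,
`mixture` and `run-all` subcommands over the same functions;
`run_pipeline()` drives the whole analysis from a YAML config and writes a
JSON manifest with per-artifact checksums.

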