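---
title: "Methods: phenotype association analysis with phenolink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotype association analysis with phenolink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenolink)
```

## The problem

Quantitative omics experiments — TMT-labelled proteomics, intact
glycopeptide (glycoproteomics) quantification, label-free or DIA data —
produce a samples x features matrix of log2 abundances alongside a
clinical table of per-sample phenotypes (pathological status, tumor
grade, stage, ...). The analytical question is almost always the same:
*which features, and which feature sets, are associated with which
phenotypes?* phenolink chains the standard answers into one
deterministic, scriptable pipeline: cohort profiling, preprocessing and
replicate-based quality control, knowledge annotation, feature discovery
(differential expression, PCA contribution ranking, clustering),
per-feature association modelling, and gene-set over-representation
analysis. Every stage emits a plain CSV so each intermediate result can
be audited.

## Data model

The expression matrix is "wide": samples as rows, features as columns,
entries on the log2 scale, `NA` for missing quantifications. Features
are either gene symbols or intact-glycopeptide ("glycoform")
identifiers of the form
`GeneName_PeptideStartSite_PeptideSequence_GlycositeNumber_GlycositePosition_GlycanComposition`
(e.g. `HYOU1_869_NATLAEQAK_1_869_N2H9`). Because gene symbols may
contain underscores while peptide sequences and glycan compositions
cannot, the parser consumes tokens from the right: the last four tokens
are peptide, site count, site position and glycan, the token before them
is the peptide start, and everything remaining is the gene. The glycan
composition accepts any letter-code + positive-count tokens (`N2H9` = 2
HexNAc, 9 Hex) without enforcing a fixed monosaccharide alphabet, since
composition codes vary between search engines. Identifiers carrying
several glycosites in one peptide are accepted with a single position
token; the site count is retained so downstream users can flag
multi-site forms for review.

Phenotype tables use the same wide layout with a kind tag —
`"(Categorical)"` or `"(Numerical)"` — appended to each column label.
The tag is the *only* type information used; nothing is inferred from
the values.

## Preprocessing and quality control

* **Log2 transform** refuses non-positive intensities and a second
  application (the flag on the matrix records the scale).
* **Median normalization** shifts each sample additively so its median
  over present values equals the target (default 0). The even-count
  median is the mean of the two central order statistics; this matters
  because the post-condition (every sample median equals the target to
  1e-9) is checked, not assumed. The operation is idempotent.
* **Noise filtration** keeps a feature iff its observed fraction is at
  least the threshold (default 0.5). The boundary is inclusive: a
  feature quantified in exactly half the samples survives, since only
  features observed in *less than* the threshold fraction are treated as
  noise.
* **Imputation** fills missing entries with a scaled minimum: the global
  matrix minimum, the sample (row) minimum, or the feature (column)
  minimum across samples. The feature-wise reading of FeatureMin —
  the minimum of this feature among all samples — is what distinguishes
  it from SampleMin; the scale factor defaults to 1 and is exposed
  because no single factor is canonical. Imputation never touches a
  present value, and all-missing rows/columns are an error (filter
  first).
* **Replicate QC** computes pairwise correlations between designated QC
  samples over co-present features (pairs sharing fewer than 3 features
  are reported undefined and excluded from the mean) and a per-feature
  coefficient of variation. The CV is computed on the **linear** scale
  (`2^value`) with the sample (n-1) standard deviation: on
  median-centred log2 data feature means sit near zero, where sd/mean is
  meaningless. A `cv_scale = "log2"` switch exists for data that were
  never normalized. Pearson is the default replicate correlation,
  Spearman selectable.

In the pipeline, QC samples are dropped after the QC report: they are
technical replicates of one base sample, and leaving them in would
pseudo-replicate that sample in every downstream test.

## Phenotype profiling

Cohort composition (level counts for categorical phenotypes; n, mean,
median, min, max for numerical ones; missing counts always included so
counts conserve n) and pairwise phenotype correlation. Categorical
phenotypes are encoded by lexicographically sorted levels mapped to
0, 1, 2, ...; the encoding map is part of the output because multi-level
encodings are ordinal at best and the sign of a correlation against an
encoded phenotype depends on the level order. Spearman is the default
method for exactly that reason; p-values use the t-approximation. Pairs
with a constant vector or fewer than 3 shared samples are reported
undefined rather than fabricated.

## Feature discovery

**Differential expression.** Two-group comparison with Student
t (Welch unequal-variance form by default — group variances in omics
comparisons are rarely equal; the pooled form is selectable), Wilcoxon
rank-sum, or their paired variants. The rank-sum test uses exact
enumeration when both groups have at most 10 samples and no ties, and
the normal approximation with continuity and tie correction otherwise;
the switch point is where enumeration stops being cheap and the
approximation error drops well below 0.02. The log2 fold change is the
difference of group medians (a median fold change is robust to the
occasional imputed extreme; mean-based FC is selectable). Raw p-values
are adjusted by the Benjamini–Hochberg step-up across all features
tested in the run — one family per comparison — and the default
significance gate is fold change > 1.5 with adjusted p < 0.01. Features
with fewer than two observations in either group are reported untested
rather than silently dropped.

**PCA contribution score.** After feature-mean centring (no unit
scaling by default — log2 abundances already share a scale; z-scoring
is selectable) the matrix is decomposed by singular value
factorization. Each feature j receives the score

$$S_j = \sum_{i=1}^{n} VR_i \cdot \frac{|V_{ij}|}{\sum_{j=1}^{m} |V_{ij}|}$$

with \(VR_i\) the explained variance ratio of component i and
\(V_{ij}\) the loading of feature j on component i. Because each
component's normalized absolute loadings sum to one, the scores conserve
the retained variance: \(\sum_j S_j = \sum_{i \le n} VR_i\) — a testable
algebraic identity used as an internal check. The number of retained
components n defaults to 10 (clipped to what the data support) and is
user-settable; the top 100 features by score form the PCA-derived
candidate set, and the 10 largest-loading features per component are
reported separately.

**Clustering.** Feature profiles are z-scored across samples (sample
sd), then clustered agglomeratively with Euclidean distance and Ward
linkage — the conventional choices for expression-pattern heatmaps; the
tree is cut at a user-defined k. Constant features cannot be z-scored
and are rejected by name (the pipeline excludes them with a note).

## Per-feature association

For each candidate feature (the union of DE calls and PCA top
contributors by default, or all features by flag) against a categorical
phenotype:

* **Correlation screen**: Pearson correlation between the feature and
  the 0/1-encoded phenotype (point-biserial), p from the
  t-approximation; associated iff p < 0.05. Spearman selectable.
* **Logistic regression**: maximum-likelihood univariate fit by IRLS
  (at most 100 iterations, deviance tolerance 1e-8), no regularization —
  the reported AUC should reflect the plain model. Complete separation
  is flagged rather than penalized away: the last iterate's fitted
  probabilities are still monotone in x, so ranking metrics remain
  valid.
* **ROC/AUC**: rank-based (Mann–Whitney with midranks), equal to the
  probability a random positive outscores a random negative; the AUC is
  in-sample, from the single fit on all samples, and is documented as
  such — no cross-validation is attempted.

Multi-level phenotypes expand to one-vs-rest contrasts, each reported
separately.

## Enrichment

Over-representation analysis of a selected gene list against GMT
gene-set collections. Glycoform identifiers are first collapsed to gene
symbols. The background defaults to the genes measured in the matrix —
the selection was made from that universe, so testing against the whole
genome would overstate enrichment; a custom background can be supplied.
The p-value is the hypergeometric upper tail \(P(X \ge k)\) (one-sided:
only over-representation is reported), BH-adjusted across tested sets.
Sets are size-filtered after background restriction (default 5–2000)
and a set covering the entire background is excluded as degenerate.
Collections such as KEGG, GO BP or MSigDB Hallmark are supplied by the
user as local GMT files; a toy generator builds planted collections for
testing.

## The synthetic cohort generator

`generate_cohort()` emulates a tumor/non-tumor TMT-style cohort: feature
baselines drawn Uniform(18, 30) on the log2 scale (reporter-intensity
magnitudes; cosmetic), a planted shift of ±`effect_log2fc` on a
`frac_de` fraction of features applied to the tumor group, Gaussian
residual noise, MCAR missingness (plus a left-censored mode that makes
minimum-value imputation meaningful), optional technical-replicate QC
samples, and a grade phenotype correlated with status. Defaults — 20
samples per group, 1000 features, 10% planted effects at |log2FC| = 1,
residual sd 0.25, no missingness — are the study conditions under which
the recovery properties are tested. It does **not** emulate isotope
interference, batch structure, correlated features or
intensity-dependent variance, so passing tests demonstrate the
statistical machinery is correct, not that any given real cohort will
behave as cleanly.

## Numerical and design choices

* Missing-value sentinels on input: empty cell, `NA`, `NaN`
  (case-insensitive), configurable.
* Matrix text round trips use 17 significant digits so present values
  survive write/read exactly.
* The DE contrast defaults to (lexicographically later level) vs
  (earlier level), so Tumor vs Non-Tumor gives "up" = higher in tumor;
  explicit `group_levels` override.
* Clustering determinism: `hclust`/Ward on a fixed input order is
  deterministic; the partition is invariant to feature order up to label
  permutation (tested).
* All pipeline randomness flows from one recorded seed; two runs with
  identical config and inputs produce byte-identical CSVs.
* Problem sizes used in the shipped tests (cohorts of 20–40 samples and
  150–1000 features, enumeration oracles up to size-12 universes) were
  chosen so every property is exercised at full strength while the whole
  suite stays fast enough to run habitually.

## Known limitations

No batch-effect correction beyond median alignment; no model-based
imputation (kNN, MinProb); no moderated-variance tests; no covariate
adjustment or cross-validated AUC; no preranked GSEA (ORA only); no
spreadsheet ingestion (export to text first); annotation is a local
left-join, not a live web-service query — URL templates only link out.

## A minimal run

```{r example, eval = FALSE}
spec <- fixture_spec(n_per_group = 10, n_features = 200, frac_de = 0.15,
                     n_qc_replicates = 3, seed = 7)
cohort <- generate_cohort(spec)
dir <- tempfile(); dir.create(dir)
write_expression_matrix(cohort$matrix, file.path(dir, "matrix.csv"))
write_phenotype_table(cohort$phenotypes, file.path(dir, "phenotypes.csv"))
cfg <- pipeline_config(file.path(dir, "matrix.csv"),
                       file.path(dir, "phenotypes.csv"),
                       out_dir = file.path(dir, "results"),
                       qc_sample_ids = cohort$qc_sample_ids, seed = 7)
manifest <- run_pipeline(cfg)
list.files(file.path(dir, "results"))
```
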