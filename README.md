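# ctpipe

`ctpipe` is an R package for the relative-quantification analysis of
RT-qPCR expression data from threshold-cycle (Ct/Cq) reports. It is aimed
at expression-profiling studies on high-density qPCR cards (e.g. 384
microRNA assays per sample) that compare exactly two treatment groups and
need a reproducible path from the instrument's text exports to a ranked
table of differentially expressed transcripts.

## The workflow

The pipeline runs five stages, producing seven output files:

1. **Parsing.** Per-sample tab-separated Ct reports in a vendor dialect
   (SDS, EDS, OpenArray, LightCycler, CFX, BioMark, or headerless Plain)
   plus a two-column treatment file (`SampleName`, `Treatment`; exactly
   two groups). The *calibrator* group is the group of the first listed
   sample, the other group is the *target*.
2. **Categorization.** Every well gets a reliability category: values
   outside a user Ct range become `Unreliable`, wells failing the
   instrument's quality flag become `Undetermined` (sentinels such as
   "Undetermined" in the source file already are). Non-`OK` values are
   then masked as `NA`.
3. **Normalization.** Six options: global mean, modified global mean
   (geometric-mean equivalent on the linear scale over the
   common-detected feature set), ΔCt against housekeeping genes (given
   explicitly or chosen by geNorm pairwise-variation stability *M* or by
   the NormFinder model-based stability ρ), quantile, and two
   rank-invariant methods (missing values are spline-pre-filled only for
   fitting).
4. **Filtering and imputation.** Features exceeding a missing-value
   percentage (strict `>`) or named on a removal list are dropped;
   remaining `NA`s are imputed by KNN, by the maximum-Ct-plus-one rule
   ("Mestdagh"), or by per-feature cubic splines.
5. **Differential expression.** Per feature: Welch/pooled t-test,
   Wilcoxon, or the rank-product permutation test, with p-value
   adjustment (BH/BY/Bonferroni/Holm/Hochberg/Hommel/none). Each row
   reports the group means on the Ct scale, `ddCt = mean_target −
   mean_calibrator`, fold change `FC = 2^−ddCt`, and the aggregated
   per-group reliability category.

QC output includes per-sample boxplots before/after normalization and the
ECDFs of per-feature coefficients of variation before/after, compared by
a two-sample Kolmogorov–Smirnov test.

## Worked example

The package ships a synthetic-data generator that emulates a two-group
card experiment (per-feature baselines, per-sample technical shifts,
spiked two-cycle effects, high-Ct dropout, failure flags):

```r
library(ctpipe)

dir <- file.path(tempdir(), "demo")
gen <- generate_synthetic(synthetic_config(
  n_features = 96, n_samples_per_group = 8, n_spiked = 10, seed = 42),
  out_dir = dir)

cfg <- pipeline_config(
  input          = dir,
  treatment_path = file.path(dir, "treatment.tsv"),
  output_dir     = file.path(dir, "out"),
  categories     = category_settings(ct_min = 10, ct_max = 38,
                                     use_flags = TRUE),
  normalization  = normalization_spec("global_mean"),
  filter         = filter_spec(max_missing_pct = 30),
  imputation     = impute_spec("knn", k = 10),
  de             = de_spec("ttest", adjust = "BH"),
  seed           = 42)
res <- run_pipeline(cfg)

head(res$de_table[, c("genes", "t.test", "p.value", "adj.p.value",
                      "ddCt", "FC")], 5)
#>    genes  t.test   p.value adj.p.value   ddCt     FC
#>  miR-043 -12.030 9.172e-09   8.805e-07  1.961 0.2569
#>  miR-014   9.981 1.307e-07   6.272e-06 -2.308 4.9510
#>  miR-054   9.039 3.215e-07   1.029e-05 -2.407 5.3020
#>  miR-028  -9.162 6.939e-07   1.665e-05  2.370 0.1934
#>  miR-090  -8.129 1.240e-06   2.185e-05  1.900 0.2679

nrow(significant_features(res$de_table))  # p < 0.05 and FC > 2 or < 0.5
#> 10
```

All ten significant features are the ten truly spiked ones
(`gen$truth$spiked_features`); `ddCt ≈ ±2` recovers the simulated
two-cycle effect and `FC = 2^−ddCt` converts it to a fold change
(negative ddCt = more abundant in the target group, FC > 1). The KS
comparison of CV distributions for this run is D = 0.969 (p ≈ 0),
reflecting the strong noise reduction from removing the simulated
per-sample shifts.

A command-line front end is installed with the package
(`inst/cli/ctpipe`): `ctpipe run --input DIR --treatment FILE --output
DIR [options]`, `ctpipe formats`, `ctpipe simulate --out DIR --seed N`.
Options can also come from a JSON config via `--config`; explicit flags
win.

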