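---
title: "ctpipe: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ctpipe: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctpipe)
```

This vignette documents the statistical model behind each pipeline stage,
the defaults and why they were chosen, and the places where the design was
genuinely open and a decision had to be made. It states no empirical claim
that the test suite or the acceptance script does not itself compute.

## The quantity being analyzed

RT-qPCR reports a threshold cycle Ct per assay and sample: the
amplification cycle at which fluorescence first exceeds a threshold.
Ct is a *negative log2 abundance* scale — one cycle less means roughly
twice the starting template. All of `ctpipe`'s arithmetic respects this:
normalizations are additive shifts on the Ct scale (multiplicative on the
linear scale), and the final effect size is

$$\Delta\Delta C_t = \overline{Ct}_{\mathrm{target}} -
\overline{Ct}_{\mathrm{calibrator}}, \qquad
\mathrm{FC} = 2^{-\Delta\Delta C_t}.$$

The calibrator is the group of the first sample in the treatment file;
this convention fixes the sign of every downstream statistic, so the
treatment file's row order is part of the analysis specification. The
`FC = 2^-ddCt` identity is enforced to 1e-12 on every output row.

## Parsing and categorization

Reports must be tab-separated with "." as the decimal separator; a comma
decimal is a hard error naming the offending row, not a silent `NA` —
silently dropping half of a European-format file would bias everything
downstream. A Ct field must be numeric or one of the missing-value
sentinels (case-insensitive `Undetermined`, `No Ct`, `NA`, empty);
anything else is an error. Missingness is carried explicitly as `NA`
rather than substituted with a fixed cycle number (a convention some
toolkits use); the imputation stage is the only place missing values are
materialized, so the choice of rule is visible and testable.

Only the SDS, EDS and Plain dialects are exercised by tests; the
OpenArray, LightCycler, CFX and BioMark entries are templates with
commonly seen column names, because vendor exports vary by software
version and no authoritative layout was available. `ct_dialect()` lets a
user adjust any of them declaratively.

Categorization assigns one label per well. Rules, in order: a sentinel
stays `Undetermined`; a numeric Ct outside `[ct_min, ct_max]` becomes
`Unreliable`; if flag checking is enabled, a failing flag forces
`Undetermined`, overriding the range label (a failed well is
uninterpretable regardless of its value, so the flag is the stronger
evidence). The default range is `[0, Inf)` — no range filtering unless
the user opts in, since sensible bounds depend on chemistry and card.
Masking replaces every non-`OK` value with `NA` but keeps the labels, so
the final table can report per-group reliability.

## Normalization

*Global mean* subtracts each sample's mean observed Ct. It assumes the
bulk of features is non-differential, and is sensitive to which features
happen to be detected in each sample. *Modified global mean* addresses
that by averaging only over the common-detected set (features observed in
every sample); on the linear scale this is division by the geometric
mean, the standard recommendation for microRNA panels.

*ΔCt* subtracts the per-sample mean of housekeeping features.
Housekeepers can be named, or estimated:

* **geNorm** scores gene $j$ by $M_j$, the mean over partners $k$ of the
  SD across samples of $Ct_j - Ct_k$ (n−1 denominator). Low M = stable.
  The selection takes genes with $M$ *below* the cutoff (default 1.5).
  The toolkit this design follows describes taking genes with "stability
  greater than 1.5", but in the pairwise-variation method 1.5 is an
  *upper* bound on acceptable M and selecting above it would pick the
  least stable genes; both the cutoff and the direction are exposed
  (`genorm_cutoff`, `genorm_direction`) for compatibility. A single-pass
  M computation is used for threshold selection; the ranking is also
  reported.
* **NormFinder** fits the model-based decomposition: after removing each
  sample's mean over genes, the per-group gene effects and intra-group
  variances are estimated (with the correction for the shared
  sample-mean subtraction, clamped at zero), the inter-group deviation
  of each gene is shrunk by its sampling variance, and
  $\rho_j = \text{mean over groups of } (|\tilde d_{ji}| +
  \sqrt{\hat\sigma^2_{ji}/n_i})$. Low ρ = stable. As a selector it
  returns the top `hk_count` genes (default 1), since the published
  method does not prescribe a count.

*Quantile* maps each sample's values onto the mean of the per-sample
sorted distributions, with linear interpolation onto a common quantile
grid when samples have different numbers of observed values, and
average-rank handling of ties. On complete data all post-normalization
sample distributions are identical.

*Rank-invariant* methods need complete data, so each feature row is first
filled with a natural cubic interpolating spline over the sample index
(`stats::spline(method = "natural")`), extrapolating at the edges; the
fills are used **only for fitting** and the original `NA` positions are
restored afterwards, because filtering and imputation are their own,
user-controlled stages. The invariant set of a sample against the
pseudo-reference (per-feature mean) is found iteratively: keep features
whose rank difference, as a fraction of the set size, is below a
threshold interpolated from 0.003 to 0.007 by average rank (the
established invariant-set defaults; the original description delegates
to its host implementation without parameters), up to 10 iterations or a
fixed point. The *scale* mode subtracts a per-sample shift (invariant-set
mean minus grand mean) using features invariant in **all** comparisons;
it removes constant offsets exactly. The *norm* mode fits a locally
weighted regression (span 0.3) through the invariant pairs, monotonized
by a running maximum — monotonicity preserves Ct ordering — and maps the
sample through the curve's inverse; values outside the fitted range are
shifted by the boundary offset. If an invariant set has fewer than 5
features the method aborts and suggests quantile normalization: these
thresholds are calibrated for hundreds of features, and on small noisy
panels the invariant set degenerates legitimately.

## Filtering and imputation

The missingness filter removes a feature when its missing percentage
*strictly exceeds* the slider, so a feature at exactly the threshold
survives. The removal list is unconditional. Filtering runs after
normalization, matching the workflow's stage order; imputation therefore
operates on normalized values.

* **Mestdagh**: each missing value becomes the feature's maximum observed
  Ct plus one cycle — the missing-equals-low-abundance reading; the
  "+1" is applied per feature because the rule speaks about a
  transcript's own detection limit. All-missing features fall back to
  the dataset-wide maximum plus one. No 40-cycle clamp is applied, since
  none is specified. Every imputed value strictly exceeds the feature's
  observed maximum (a tested invariant).
* **KNN**: neighbor distance is the RMS difference over co-observed
  samples (scaling by overlap keeps distances comparable across
  missingness patterns); the k (default 10) nearest features observed at
  the target sample contribute a 1/distance-weighted mean, with equal
  weights among exact duplicates (distance 0); a feature with no usable
  neighbor falls back to its own mean.
* **Cubic**: the same natural-spline rule as the normalization pre-fill,
  per feature over the sample index; features with fewer than two
  observations fall back to the Mestdagh rule (logged).

## Differential expression

The t-test defaults to Welch (unequal variances) — the safer choice when
nothing is known about group variances; a pooled-variance switch exists.
Zero-variance features do not abort the table: equal-mean constant
features report statistic 0 and p = 1, perfectly separated constant
features report an infinite statistic and p = 0, both logged as
degenerate. The Wilcoxon test is exact when the combined sample size is
at most 12 without ties, and a tie-corrected normal approximation with
continuity correction otherwise.

The rank-product test ranks, within every cross-group sample pair, the
target-minus-calibrator differences in both directions and takes the
geometric mean of each gene's ranks. Significance is the expected number
of permuted rank products at or below the observed one divided by the
gene's rank (a percentage of false prediction, not a p-value in the
strict sense; it is clipped to 1 before adjustment). The permutation
scheme shuffles the per-pair differences across genes; under it a
permuted gene's ranks are uniform and independent across pairs, which is
what the `exact = TRUE` mode enumerates on small instances — the test
suite verifies this against a full joint-permutation brute force.
Replicated feature names can be collapsed by per-sample means before
testing (mean is the standard collapse; the aggregated category is `OK`
only if all replicate wells are `OK`).

Group categories are aggregated per gene: *stringent* mode reports `OK`
only when every sample in the group is `OK`; *lenient* mode when strictly
more than half are. The majority threshold is this package's contract —
the original interface exposes a stringency toggle without defining the
lenient rule.

`method = "none"` short-circuits: the DE output is a header-only table,
and the other six outputs are still produced.

## QC report

Coefficients of variation are computed on the Ct scale
($\mathrm{sd}/|\mathrm{mean}|$ per feature), as the host toolkit of the
original workflow does. Centering normalizations can push feature means
toward zero, so features with $|\mathrm{mean}| < 10^{-8}$ (or fewer than
two observations) are dropped and logged rather than producing infinite
CVs. "Pre" is the masked, categorized dataset; "post" the normalized one,
matching the original figure legends. The two CV distributions are
compared with a two-sample Kolmogorov–Smirnov test using the asymptotic
p-value — feature counts are in the hundreds, where the asymptotic
formula is adequate and the exact computation would reject ties anyway.

## The synthetic generator

`generate_synthetic()` draws
$Ct_{gs} = b_g + t_s + \delta_g\,[s \in \mathrm{target}] + \varepsilon_{gs}$
with per-feature baselines $b_g \sim N(25, 3^2)$ cycles, per-sample
technical shifts $t_s \sim N(0, 1)$, spiked effects $\delta_g = \pm 2$
cycles (alternating sign) on `n_spiked` features, and noise
$\varepsilon \sim N(0, 0.5^2)$. Defaults mirror a 384-feature card with
8 + 8 samples; the baseline, spread and detection limit are typical
values for microRNA cards (Ct mostly 20–35, detection failing above
~35 cycles). Dropout is missing-not-at-random: the probability rises
linearly from 0 at the 35-cycle threshold to 1 at 40 — the same
low-abundance mechanism the Mestdagh rule assumes. A 2% "Failed" flag
rate exercises the flag path.

What the generator does *not* emulate: correlated feature blocks,
amplification-efficiency differences between assays, plate/batch layout
effects, heavy-tailed or sample-dependent noise, and informative
missingness beyond the high-Ct mechanism. A green simulation test
therefore establishes that the pipeline recovers the stated additive
model — not that it is robust to everything real cards do.

## Numerical conventions

* Tabular outputs render missing values as `NA` and write doubles with
  the shortest representation that parses back bit-identically
  (falling back to 17 significant digits), so write→read round-trips
  are exact.
* Global-mean post-normalization sample means are zero to 1e-9 (tested).
* Rank ties use average ranks throughout (quantile mapping, rank
  product, Wilcoxon fallback).
* All stochastic stages (rank-product permutations, the generator)
  consume an explicit seed; identical configuration and seed give
  byte-identical tabular outputs (tested).
* The run configuration can be supplied as JSON. (YAML was considered;
  the installation targets environments without a YAML parser for R,
  and JSON covers the same schema with `jsonlite` only.)

## Known limitations

* Only two-group designs; no multi-group or paired-covariate models, no
  moderated/empirical-Bayes tests.
* Absolute quantification (standard curves) and efficiency-corrected
  models are out of scope.
* The four untested vendor dialects are templates, not certified
  parsers.
* The NormFinder estimator is this package's own implementation of the
  published model; it reproduces the model's qualitative behavior
  (tested against an independent re-derivation) but is not guaranteed to
  match any specific third-party implementation to the last digit.
* The embedded published significant-feature tables are transcriptions
  used as regression fixtures; reproducing the underlying studies'
  statistics end-to-end requires their raw public data and unpublished
  missing-value handling choices, and is deliberately not part of the
  test surface.
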