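#' Differential expression specification
#'
#' @param method `"ttest"`, `"wilcoxon"`, `"rankprod"`, or `"none"` (skip
#'   testing).
#' @param alternative `"two_sided"`, `"less"` or `"greater"` (direction of
#'   the calibrator-minus-target contrast).
#' @param paired paired analysis (pairing by sample order within groups;
#'   requires equal group sizes).
#' @param replicates collapse replicated feature names by per-sample mean
#'   before testing.
#' @param stringent category aggregation: `TRUE` reports a group as "OK"
#'   only if every sample is OK; `FALSE` if strictly more than half are.
#' @param adjust p-value adjustment: one of
#'   `c("BH", "BY", "bonferroni", "holm", "hochberg", "hommel", "none")`.
#' @param var_equal pooled-variance t-test instead of Welch.
#' @param permutations permutation count for the rank-product test.
#' @param seed RNG seed for the permutations.
#' @return A `DESpec` list.
#' @export
de_spec <- function(method = c("ttest", "wilcoxon", "rankprod", "none"),
                    alternative = c("two_sided", "less", "greater"),
                    paired = FALSE, replicates = FALSE, stringent = TRUE,
                    adjust = c("BH", "BY", "bonferroni", "holm", "hochberg",
                               "hommel", "none"),
                    var_equal = FALSE, permutations = 1000L, seed = NULL) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  adjust <- match.arg(adjust)
  permutations <- as.integer(permutations)
  if (method == "rankprod" && permutations < 1L)
    stop("permutations must be >= 1", call. = FALSE)
  structure(list(method = method, alternative = alternative,
                 paired = isTRUE(paired), replicates = isTRUE(replicates),
                 stringent = isTRUE(stringent), adjust = adjust,
                 var_equal = isTRUE(var_equal), permutations = permutations,
                 seed = seed),
            class = "DESpec")
}

#' Group means, ddCt and fold change for one feature
#'
#' ddCt is the target group mean minus the calibrator group mean of the
#' (normalized) Ct values; the fold change is `2^-ddCt`, so lower Ct in
#' the target group (higher abundance) gives FC > 1.
#'
#' @param ds a [ct_dataset()].
#' @param treatment a [treatment_map()].
#' @param feature feature name (must identify one row, or its replicates
#'   are averaged).
#' @return Named list: `mean_calibrator`, `mean_target`, `ddCt`, `FC`.
#' @export
group_summary <- function(ds, treatment, feature) {
  rows <- which(ds$feature_names == feature)
  if (!length(rows)) stop("feature not found: ", feature, call. = FALSE)
  gi <- group_indices(treatment, ds$sample_names)
  vals <- colMeans(ds$ct[rows, , drop = FALSE], na.rm = TRUE)
  mc <- mean(vals[gi$calibrator], na.rm = TRUE)
  mt <- mean(vals[gi$target], na.rm = TRUE)
  if (!is.finite(mc) || !is.finite(mt))
    stop("feature ", feature, " entirely missing in one group", call. = FALSE)
  dd <- mt - mc
  list(mean_calibrator = mc, mean_target = mt, ddCt = dd,
       FC = fc_from_ddct(dd))
}

#' Fold change from a ddCt value
#'
#' `FC = 2^-ddCt`, optionally rounded to the printed precision.
#'
#' @param ddct ddCt value(s) in cycles.
#' @param digits round to this many decimals (`NULL` = no rounding).
#' @return Fold change(s).
#' @export
fc_from_ddct <- function(ddct, digits = NULL) {
  fc <- 2^(-ddct)
  if (!is.null(digits)) fc <- round(fc, digits)
  fc
}

#' Adjust p-values for multiple testing
#'
#' Thin validated wrapper over the standard step-up/step-down procedures.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param method adjustment method (see [de_spec()]).
#' @return Adjusted p-values, same order as input.
#' @export
adjust_pvalues <- function(p, method = "BH") {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p, method = method)
}

#' Aggregate per-sample categories of a group
#'
#' @param categories character vector of per-sample categories for one
#'   feature in one group.
#' @param stringent `TRUE`: "OK" only if all samples are OK; `FALSE`:
#'   "OK" if strictly more than half are OK.
#' @return `"OK"` or `"Undetermined"`.
#' @export
aggregate_category <- function(categories, stringent = TRUE) {
  if (!length(categories)) stop("empty category list", call. = FALSE)
  ok <- categories == "OK"
  if (if (stringent) all(ok) else mean(ok) > 0.5) "OK" else "Undetermined"
}

map_alternative <- function(a)
  switch(a, two_sided = "two.sided", less = "less", greater = "greater")

# collapse replicated feature names by per-sample mean; a collapsed cell is
# "OK" only if all its replicate cells are OK
collapse_replicates <- function(ds) {
  if (!anyDuplicated(ds$feature_names)) return(ds)
  feats <- unique(ds$feature_names)
  ct <- matrix(NA_real_, length(feats), ncol(ds$ct))
  cats <- matrix("OK", length(feats), ncol(ds$ct))
  for (i in seq_along(feats)) {
    rows <- which(ds$feature_names == feats[i])
    ct[i, ] <- colMeans(ds$ct[rows, , drop = FALSE], na.rm = TRUE)
    all_ok <- apply(ds$categories[rows, , drop = FALSE] == "OK", 2L, all)
    cats[i, ] <- ifelse(all_ok, "OK", "Undetermined")
  }
  ct[!is.finite(ct)] <- NA_real_
  ct_dataset(ct, feature_names = feats, sample_names = ds$sample_names,
             categories = cats)
}

de_result_row <- function(ds, treatment, feature, stat, p, stringent) {
  gs <- group_summary(ds, treatment, feature)
  row <- which(ds$feature_names == feature)[1L]
  gi <- group_indices(treatment, ds$sample_names)
  data.frame(
    genes = feature, statistic = stat, p.value = p,
    ddCt = gs$ddCt, FC = gs$FC,
    meanCalibrator = gs$mean_calibrator, meanTarget = gs$mean_target,
    categoryCalibrator = aggregate_category(ds$categories[row, gi$calibrator],
                                            stringent),
    categoryTarget = aggregate_category(ds$categories[row, gi$target],
                                        stringent),
    stringsAsFactors = FALSE)
}

run_two_sample_tests <- function(ds, treatment, spec, test_fun) {
  gi <- group_indices(treatment, ds$sample_names)
  if (spec$paired && length(gi$calibrator) != length(gi$target))
    stop("paired analysis requires equal group sizes", call. = FALSE)
  feats <- unique(ds$feature_names)
  rows <- lapply(feats, function(f) {
    r <- which(ds$feature_names == f)[1L]
    x <- ds$ct[r, gi$calibrator]; y <- ds$ct[r, gi$target]
    if (spec$paired) {
      keep <- !is.na(x) & !is.na(y)
      x <- x[keep]; y <- y[keep]
    } else {
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
    }
    res <- test_fun(x, y)
    de_result_row(ds, treatment, f, res$stat, res$p, spec$stringent)
  })
  tab <- do.call(rbind, rows)
  tab$adj.p.value <- adjust_pvalues(tab$p.value, spec$adjust)
  tab[order(tab$p.value), c("genes", "statistic", "p.value", "adj.p.value",
                            "ddCt", "FC", "meanCalibrator", "meanTarget",
                            "categoryCalibrator", "categoryTarget")]
}

#' Two-group t-test differential expression
#'
#' Per feature, a two-sample t-test of calibrator versus target on the
#' available (non-missing) values — Welch by default, pooled variance with
#' `var_equal = TRUE`, paired with `paired = TRUE`. Degenerate features
#' (zero variance in both groups) are reported with statistic 0 and p = 1
#' when the means are equal, and with an infinite statistic and p = 0 when
#' they differ (perfect separation); both cases are listed in the
#' `"degenerate"` attribute rather than aborting the table.
#'
#' @param ds a [ct_dataset()] (typically normalized and imputed).
#' @param treatment a [treatment_map()].
#' @param spec a [de_spec()].
#' @return A `DEResultTable` data.frame sorted by ascending p-value with
#'   columns genes, t.test, p.value, adj.p.value, ddCt, FC,
#'   meanCalibrator, meanTarget, categoryCalibrator, categoryTarget.
#' @export
ttest_de <- function(ds, treatment, spec = de_spec("ttest")) {
  ds <- if (spec$replicates) collapse_replicates(ds) else ds
  degenerate <- character()
  alt <- map_alternative(spec$alternative)
  tfun <- function(x, y) {
    res <- tryCatch(
      t.test(x, y, alternative = alt, paired = spec$paired,
             var.equal = spec$var_equal),
      error = function(e) NULL)
    if (is.null(res)) {
      mdiff <- if (spec$paired) mean(x - y) else mean(x) - mean(y)
      if (!is.finite(mdiff)) list(stat = NA_real_, p = NA_real_, deg = TRUE)
      else if (isTRUE(all.equal(mdiff, 0)))
        list(stat = 0, p = 1, deg = TRUE)
      else list(stat = sign(mdiff) * Inf, p = 0, deg = TRUE)
    } else list(stat = unname(res$statistic), p = res$p.value, deg = FALSE)
  }
  wrapped <- function(x, y) {
    r <- tfun(x, y)
    if (r$deg) degenerate <<- c(degenerate, "x")
    r
  }
  tab <- run_two_sample_tests(ds, treatment, spec, wrapped)
  names(tab)[names(tab) == "statistic"] <- "t.test"
  attr(tab, "degenerate") <- length(degenerate)
  class(tab) <- c("DEResultTable", class(tab))
  tab
}

#' Two-group Wilcoxon differential expression
#'
#' Per feature, a Mann-Whitney test (unpaired) or Wilcoxon signed-rank
#' test (paired) of calibrator versus target. The p-value is exact when
#' the combined sample size is at most 12 and there are no ties, and a
#' normal approximation with continuity and tie correction otherwise.
#'
#' @inheritParams ttest_de
#' @return A `DEResultTable` with statistic column `W`.
#' @export
wilcoxon_de <- function(ds, treatment, spec = de_spec("wilcoxon")) {
  ds <- if (spec$replicates) collapse_replicates(ds) else ds
  alt <- map_alternative(spec$alternative)
  wfun <- function(x, y) {
    exact <- (length(x) + length(y)) <= 12L &&
      !anyDuplicated(if (spec$paired) abs(x - y) else c(x, y))
    res <- tryCatch(
      suppressWarnings(
        wilcox.test(x, y, alternative = alt, paired = spec$paired,
                    exact = exact, correct = TRUE)),
      error = function(e) NULL)
    if (is.null(res) || is.na(res$p.value))
      list(stat = 0, p = 1) else
        list(stat = unname(res$statistic), p = res$p.value)
  }
  tab <- run_two_sample_tests(ds, treatment, spec, wfun)
  names(tab)[names(tab) == "statistic"] <- "W"
  class(tab) <- c("DEResultTable", class(tab))
  tab
}

# rank matrices over all cross-group sample pairs:
# diff_g(pair) = ct_target - ct_calibrator; rank 1 in "up" = most negative
# difference (most up-regulated in target on the Ct scale), rank 1 in
# "down" = most positive
rankprod_ranks <- function(x_cal, x_tar) {
  pairs <- expand.grid(i = seq_len(ncol(x_cal)), j = seq_len(ncol(x_tar)))
  up <- down <- matrix(NA_real_, nrow(x_cal), nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    d <- x_tar[, pairs$j[p]] - x_cal[, pairs$i[p]]
    up[, p] <- rank(d)
    down[, p] <- rank(-d)
  }
  list(up = up, down = down)
}

geom_mean_rows <- function(r) exp(rowMeans(log(r)))

# expected count of permuted-gene rank products <= each observed value.
# Under the permutation scheme (independent shuffles of the per-pair
# differences across genes), each permuted gene's ranks are uniform on
# 1..G, independent across pairs, so
# E[#{g': RP*_g' <= x}] = G * P(geomean of P iid uniform ranks <= x).
rankprod_expected_counts <- function(rp_obs, G, P, nperm = NULL,
                                     exact = FALSE) {
  if (exact) {
    if (G^P > 2e6)
      stop("exact rank-product enumeration infeasible for G^P = ", G^P,
           call. = FALSE)
    combos <- as.matrix(expand.grid(rep(list(seq_len(G)), P)))
    rp_null <- geom_mean_rows(combos)
    vapply(rp_obs, function(x) G * mean(rp_null <= x + 1e-12), 0)
  } else {
    counts <- numeric(length(rp_obs))
    ord <- order(rp_obs)
    for (b in seq_len(nperm)) {
      ranks <- matrix(0, G, P)
      for (p in seq_len(P)) ranks[, p] <- sample.int(G)
      rp_null <- sort(geom_mean_rows(ranks))
      counts[ord] <- counts[ord] +
        findInterval(rp_obs[ord] + 1e-12, rp_null)
    }
    counts / nperm
  }
}

#' Rank-product differential expression
#'
#' For every cross-group sample pair, genes are ranked by the
#' target-minus-calibrator Ct difference in both directions (rank 1 = most
#' up-regulated in the target, and separately rank 1 = most
#' down-regulated). The rank product of a gene is the geometric mean of
#' its ranks over all pairs; small values in either direction indicate
#' consistent regulation. Significance is a percentage of false prediction
#' (pfp): the expected number of permuted-gene rank products at or below
#' the observed one (estimated from `permutations` independent shuffles of
#' the per-pair differences across genes, or computed exactly with
#' `exact = TRUE` on small instances), divided by the gene's rank-product
#' rank. The reported statistic is the better-direction RP and its pfp is
#' the p-value (clipped to 1 for adjustment).
#'
#' @inheritParams ttest_de
#' @param exact compute the permutation null by exhaustive enumeration
#'   (small instances only).
#' @return A `DEResultTable` with statistic column `RP` and an `rp_detail`
#'   attribute (per-gene RP/pfp in both directions).
#' @export
rankprod_de <- function(ds, treatment, spec = de_spec("rankprod"),
                        exact = FALSE) {
  ds <- if (spec$replicates) collapse_replicates(ds) else ds
  if (anyNA(ds$ct))
    stop("rank product requires complete data; impute first", call. = FALSE)
  gi <- group_indices(treatment, ds$sample_names)
  x_cal <- ds$ct[, gi$calibrator, drop = FALSE]
  x_tar <- ds$ct[, gi$target, drop = FALSE]
  G <- nrow(ds$ct); P <- ncol(x_cal) * ncol(x_tar)
  rk <- rankprod_ranks(x_cal, x_tar)
  rp_up <- geom_mean_rows(rk$up)
  rp_down <- geom_mean_rows(rk$down)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  pfp <- function(rp) {
    e <- rankprod_expected_counts(rp, G, P, nperm = spec$permutations,
                                  exact = exact)
    e / rank(rp, ties.method = "average")
  }
  pfp_up <- pfp(rp_up); pfp_down <- pfp(rp_down)
  use_up <- rp_up <= rp_down
  stat <- ifelse(use_up, rp_up, rp_down)
  pval <- pmin(1, ifelse(use_up, pfp_up, pfp_down))
  feats <- ds$feature_names
  rows <- lapply(seq_along(feats), function(i)
    de_result_row(ds, treatment, feats[i], stat[i], pval[i], spec$stringent))
  tab <- do.call(rbind, rows)
  tab$adj.p.value <- adjust_pvalues(tab$p.value, spec$adjust)
  tab <- tab[order(tab$p.value), c("genes", "statistic", "p.value",
                                   "adj.p.value", "ddCt", "FC",
                                   "meanCalibrator", "meanTarget",
                                   "categoryCalibrator", "categoryTarget")]
  names(tab)[names(tab) == "statistic"] <- "RP"
  attr(tab, "rp_detail") <- data.frame(
    genes = feats, RP_up = rp_up, RP_down = rp_down,
    pfp_up = pfp_up, pfp_down = pfp_down, stringsAsFactors = FALSE)
  class(tab) <- c("DEResultTable", class(tab))
  tab
}

#' Run the configured differential expression analysis
#'
#' Dispatcher over [ttest_de()], [wilcoxon_de()], [rankprod_de()] and the
#' `"none"` short-circuit (an empty table with the standard header).
#'
#' @inheritParams ttest_de
#' @return A `DEResultTable`.
#' @export
run_de <- function(ds, treatment, spec = de_spec()) {
  stopifnot(inherits(spec, "DESpec"))
  if (spec$method == "none") {
    tab <- data.frame(genes = character(), t.test = numeric(),
                      p.value = numeric(), adj.p.value = numeric(),
                      ddCt = numeric(), FC = numeric(),
                      meanCalibrator = numeric(), meanTarget = numeric(),
                      categoryCalibrator = character(),
                      categoryTarget = character(), stringsAsFactors = FALSE)
    class(tab) <- c("DEResultTable", class(tab))
    return(tab)
  }
  switch(spec$method,
         ttest = ttest_de(ds, treatment, spec),
         wilcoxon = wilcoxon_de(ds, treatment, spec),
         rankprod = rankprod_de(ds, treatment, spec))
}

#' Write a differential expression table
#'
#' Tab-separated, "." decimal, columns in the standard order, one row per
#' feature sorted by ascending p-value.
#'
#' @param tab a `DEResultTable`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Filter a DE table for significant features
#'
#' The significance convention of the reported tables: raw p below
#' `alpha` and fold change above `fc_high` (up-regulated in the target
#' group) or below `fc_low` (down-regulated).
#'
#' @param tab a `DEResultTable` (or any data.frame with `p.value` and
#'   `FC`).
#' @param alpha p-value threshold (default 0.05).
#' @param fc_high,fc_low fold-change thresholds (defaults 2 and 0.5).
#' @param direction `"both"`, `"up"` (FC > fc_high only) or `"down"`
#'   (FC < fc_low only).
#' @return The filtered table.
#' @export
significant_features <- function(tab, alpha = 0.05, fc_high = 2,
                                 fc_low = 0.5,
                                 direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  sig <- tab$p.value < alpha
  up <- tab$FC > fc_high
  down <- tab$FC < fc_low
  keep <- switch(direction, both = sig & (up | down), up = sig & up,
                 down = sig & down)
  tab[keep, , drop = FALSE]
}
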