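#' Fill missing values per row by a natural cubic spline
#'
#' For each row with at least 2 observed values, fits a natural cubic
#' interpolating spline over the sample index (1..n, treatment-file
#' order) through the observed points and evaluates it at the missing
#' positions; leading/trailing gaps are spline extrapolations. Observed
#' entries are never altered. Rows with fewer than 2 observed values are
#' left untouched and reported in the `"unfilled_rows"` attribute.
#'
#' This pre-fill is what lets the rank-invariant normalizations operate on
#' data with missing Ct values; it is also the "cubic" imputation rule.
#'
#' @param m numeric matrix (features x samples) possibly containing `NA`.
#' @return The filled matrix with attribute `unfilled_rows` (integer row
#'   indices left untouched).
#' @export
spline_fill <- function(m) {
  m <- as.matrix(m)
  unfilled <- integer()
  for (i in seq_len(nrow(m))) {
    obs <- which(!is.na(m[i, ]))
    gap <- which(is.na(m[i, ]))
    if (!length(gap)) next
    if (length(obs) < 2L) { unfilled <- c(unfilled, i); next }
    m[i, gap] <- spline(x = obs, y = m[i, obs], xout = gap,
                        method = "natural")$y
  }
  attr(m, "unfilled_rows") <- unfilled
  m
}

# shared helper: subtract a per-sample scalar from all non-missing cells
sweep_samples <- function(ds, offsets) {
  set_ct(ds, sweep(ds$ct, 2L, offsets))
}

#' Global mean normalization
#'
#' Subtracts from each sample the arithmetic mean of that sample's
#' non-missing Ct values. Missing cells stay missing.
#'
#' @param ds a [ct_dataset()].
#' @return The normalized dataset.
#' @export
normalize_global_mean <- function(ds) {
  stopifnot(inherits(ds, "CtDataset"))
  n_obs <- colSums(!is.na(ds$ct))
  if (any(n_obs == 0L))
    stop("sample(s) without any observed Ct value: ",
         paste(ds$sample_names[n_obs == 0L], collapse = ", "), call. = FALSE)
  sweep_samples(ds, colMeans(ds$ct, na.rm = TRUE))
}

#' Modified global mean normalization
#'
#' Centers each sample on the mean Ct of the common-detected feature set
#' (features observed in every sample). On the linear `2^-Ct` scale this
#' equals division by the geometric mean over that set, the behaviour that
#' motivated the "modified global mean" for microRNA panels where
#' sample-specific detection failures would otherwise bias the global
#' mean.
#'
#' @param ds a [ct_dataset()].
#' @return The normalized dataset.
#' @export
normalize_modified_global_mean <- function(ds) {
  stopifnot(inherits(ds, "CtDataset"))
  common <- !apply(is.na(ds$ct), 1L, any)
  if (!any(common))
    stop("no feature is observed in every sample; cannot form the ",
         "common-detected set", call. = FALSE)
  sweep_samples(ds, colMeans(ds$ct[common, , drop = FALSE]))
}

#' Delta-Ct normalization against housekeeping genes
#'
#' Subtracts from each sample the arithmetic mean Ct of the housekeeping
#' features in that sample. Housekeepers can be given explicitly or
#' estimated from the data by [genorm_stability()] (all genes with M below
#' the cutoff) or [normfinder_stability()] (the `hk_count` most stable
#' genes). A housekeeper missing in a sample is dropped from that sample's
#' reference mean.
#'
#' @param ds a [ct_dataset()].
#' @param housekeepers explicit feature names (selector `"explicit"`).
#' @param selector `"explicit"`, `"genorm"` or `"normfinder"`.
#' @param treatment a [treatment_map()]; required for `"normfinder"`.
#' @param genorm_cutoff stability cutoff for geNorm selection.
#' @param genorm_direction see [genorm_stability()].
#' @param hk_count number of genes to take from the NormFinder ranking.
#' @return A list with `dataset` (normalized) and `stability` (a
#'   `StabilityReport`, or a minimal report for explicit housekeepers).
#' @export
normalize_deltact <- function(ds, housekeepers = NULL,
                              selector = c("explicit", "genorm", "normfinder"),
                              treatment = NULL, genorm_cutoff = 1.5,
                              genorm_direction = "below", hk_count = 1L) {
  stopifnot(inherits(ds, "CtDataset"))
  selector <- match.arg(selector)
  report <- switch(selector,
    explicit = {
      if (is.null(housekeepers) || !length(housekeepers))
        stop("deltact with selector='explicit' requires housekeepers",
             call. = FALSE)
      absent <- setdiff(housekeepers, ds$feature_names)
      if (length(absent))
        stop("housekeeper(s) absent from the dataset: ",
             paste(absent, collapse = ", "), call. = FALSE)
      structure(list(scores = setNames(rep(NA_real_, length(housekeepers)),
                                       housekeepers),
                     selected = housekeepers, ranking = housekeepers,
                     excluded = character(), method = "explicit"),
                class = "StabilityReport")
    },
    genorm = genorm_stability(ds$ct, cutoff = genorm_cutoff,
                              direction = genorm_direction),
    normfinder = {
      if (is.null(treatment))
        stop("selector='normfinder' requires a treatment map", call. = FALSE)
      rep_ <- normfinder_stability(ds$ct, treatment)
      rep_$selected <- head(rep_$ranking, hk_count)
      rep_
    })
  hk <- report$selected
  if (!length(hk))
    stop("housekeeper selection is empty (selector=", selector, ")",
         call. = FALSE)
  rows <- which(ds$feature_names %in% hk)
  ref <- colMeans(ds$ct[rows, , drop = FALSE], na.rm = TRUE)
  if (anyNA(ref))
    stop("all housekeepers missing in sample(s): ",
         paste(ds$sample_names[is.na(ref)], collapse = ", "), call. = FALSE)
  list(dataset = sweep_samples(ds, ref), stability = report)
}

#' Quantile normalization
#'
#' Classical quantile normalization, missing-value aware: the reference
#' distribution is the mean across samples of the per-sample sorted
#' non-missing values interpolated onto a common quantile grid; each
#' observed value is replaced by the reference value at its within-sample
#' quantile (ties get the average rank). Missing cells stay missing. On
#' complete data all post-normalization sample distributions are
#' identical.
#'
#' @param ds a [ct_dataset()].
#' @return The normalized dataset.
#' @export
normalize_quantile <- function(ds) {
  stopifnot(inherits(ds, "CtDataset"))
  x <- ds$ct
  if (ncol(x) < 2L) stop("quantile normalization needs >= 2 samples",
                         call. = FALSE)
  n_obs <- colSums(!is.na(x))
  if (any(n_obs == 0L))
    stop("sample(s) without any observed Ct value: ",
         paste(ds$sample_names[n_obs == 0L], collapse = ", "), call. = FALSE)
  ngrid <- max(n_obs)
  grid <- if (ngrid == 1L) 0.5 else (seq_len(ngrid) - 1) / (ngrid - 1)
  ref_cols <- vapply(seq_len(ncol(x)), function(j) {
    v <- sort(x[!is.na(x[, j]), j])
    p <- if (length(v) == 1L) 0.5 else (seq_along(v) - 1) / (length(v) - 1)
    approx(p, v, xout = grid, rule = 2, ties = "ordered")$y
  }, numeric(ngrid))
  ref <- rowMeans(matrix(ref_cols, nrow = ngrid))
  out <- x
  for (j in seq_len(ncol(x))) {
    obs <- which(!is.na(x[, j]))
    nj <- length(obs)
    p <- if (nj == 1L) 0.5 else (rank(x[obs, j], ties.method = "average") - 1) /
      (nj - 1)
    out[obs, j] <- if (ngrid == 1L) ref else
      approx(grid, ref, xout = p, rule = 2)$y
  }
  set_ct(ds, out)
}

# iterative approximately-rank-invariant feature selection of one sample
# against the reference; trimmed rank-difference threshold interpolated
# between lo and hi by average rank
invariant_set <- function(ref, sample_values, thresholds = c(0.003, 0.007),
                          max_iter = 10L) {
  keep <- seq_along(ref)
  for (it in seq_len(max_iter)) {
    np <- length(keep)
    rr <- rank(ref[keep]); rs <- rank(sample_values[keep])
    prd <- abs(rr - rs) / np
    avg <- (rr + rs) / (2 * np)
    td <- thresholds[1L] + diff(thresholds) * avg
    ok <- prd < td
    if (all(ok)) break
    keep <- keep[ok]
    if (!length(keep)) break
  }
  keep
}

#' Rank-invariant normalization
#'
#' Normalizes each sample against a pseudo-reference (the per-feature mean
#' across samples) using the set of approximately rank-invariant features.
#' Because rank-invariant selection requires complete data, missing values
#' are first filled per feature with [spline_fill()]; the fills are used
#' only for fitting and the original missing positions are restored in the
#' output.
#'
#' * `mode = "norm"`: per sample, select the rank-invariant set versus the
#'   reference, fit a monotone smooth curve (locally weighted regression,
#'   span 0.3, monotonized) through the (reference, sample) pairs of that
#'   set, and map the whole sample through the inverse of the curve onto
#'   the reference scale; values outside the fitted range are shifted by
#'   the boundary offset.
#' * `mode = "scale"`: features rank-invariant in every sample-vs-reference
#'   comparison define a per-sample additive shift (mean of the invariant
#'   features in the sample minus their grand mean), which is subtracted —
#'   a pure per-sample shift that removes constant offsets exactly.
#'
#' @param ds a [ct_dataset()].
#' @param mode `"norm"` or `"scale"`.
#' @param min_invariant smallest admissible invariant set (default 5);
#'   below it the method aborts advising quantile normalization.
#' @return The normalized dataset.
#' @export
normalize_rank_invariant <- function(ds, mode = c("norm", "scale"),
                                     min_invariant = 5L) {
  stopifnot(inherits(ds, "CtDataset"))
  mode <- match.arg(mode)
  x <- ds$ct
  if (ncol(x) < 2L) stop("rank-invariant normalization needs >= 2 samples",
                         call. = FALSE)
  filled <- spline_fill(x)
  unfilled <- attr(filled, "unfilled_rows")
  work_rows <- setdiff(seq_len(nrow(x)), unfilled)
  w <- filled[work_rows, , drop = FALSE]
  ref <- rowMeans(w)
  inv_sets <- lapply(seq_len(ncol(w)), function(j) invariant_set(ref, w[, j]))
  out <- x

  if (mode == "scale") {
    inv <- Reduce(intersect, inv_sets)
    if (length(inv) < min_invariant)
      stop("rank-invariant set too small (", length(inv), " < ",
           min_invariant, "); consider quantile normalization", call. = FALSE)
    shift <- colMeans(w[inv, , drop = FALSE]) - mean(w[inv, ])
    out <- sweep(x, 2L, shift)
  } else {
    for (j in seq_len(ncol(w))) {
      inv <- inv_sets[[j]]
      if (length(inv) < min_invariant)
        stop("rank-invariant set too small for sample ",
             ds$sample_names[j], " (", length(inv), " < ", min_invariant,
             "); consider quantile normalization", call. = FALSE)
      fit <- lowess(ref[inv], w[inv, j], f = 0.3)
      fx <- fit$x
      fy <- cummax(fit$y)  # enforce a monotone curve on the Ct scale
      dup <- duplicated(fy)
      fx <- fx[!dup]; fy <- fy[!dup]
      v <- x[work_rows, j]
      obs <- which(!is.na(v))
      vv <- v[obs]
      mapped <- vv
      if (length(fy) >= 2L) {
        inside <- vv >= fy[1L] & vv <= fy[length(fy)]
        mapped[inside] <- approx(fy, fx, xout = vv[inside])$y
        mapped[vv < fy[1L]] <- vv[vv < fy[1L]] - (fy[1L] - fx[1L])
        mapped[vv > fy[length(fy)]] <- vv[vv > fy[length(fy)]] -
          (fy[length(fy)] - fx[length(fx)])
      } else {
        mapped <- vv - (fy[1L] - fx[1L])
      }
      out[work_rows[obs], j] <- mapped
    }
  }
  out[is.na(x)] <- NA_real_
  set_ct(ds, out)
}

#' Normalization specification and dispatcher
#'
#' `normalization_spec()` captures the normalization choice; `normalize_ct()`
#' applies it. Methods: `"global_mean"`, `"modified_global_mean"`,
#' `"deltact"`, `"quantile"`, `"norm_rank_invariant"`,
#' `"scale_rank_invariant"`.
#'
#' @param method normalization method name.
#' @param housekeepers optional housekeeping feature names (deltact).
#' @param hk_selector `"explicit"`, `"genorm"` or `"normfinder"` (deltact).
#' @param genorm_cutoff,genorm_direction,hk_count see [normalize_deltact()].
#' @return `normalization_spec()`: a `NormalizationSpec`;
#'   `normalize_ct()`: a `NormalizationResult` list with `dataset`,
#'   `method` and `stability` (NULL unless deltact).
#' @export
normalization_spec <- function(method = c("global_mean", "modified_global_mean",
                                          "deltact", "quantile",
                                          "norm_rank_invariant",
                                          "scale_rank_invariant"),
                               housekeepers = NULL,
                               hk_selector = c("explicit", "genorm",
                                               "normfinder"),
                               genorm_cutoff = 1.5,
                               genorm_direction = "below", hk_count = 1L) {
  method <- match.arg(method)
  hk_selector <- match.arg(hk_selector)
  if (method == "deltact" && hk_selector == "explicit" &&
      (is.null(housekeepers) || !length(housekeepers)))
    stop("deltact requires housekeepers or hk_selector in ",
         "{'genorm', 'normfinder'}", call. = FALSE)
  structure(list(method = method, housekeepers = housekeepers,
                 hk_selector = hk_selector, genorm_cutoff = genorm_cutoff,
                 genorm_direction = genorm_direction, hk_count = hk_count),
            class = "NormalizationSpec")
}

#' @rdname normalization_spec
#' @param ds a [ct_dataset()].
#' @param spec a `NormalizationSpec`.
#' @param treatment a [treatment_map()] (needed for NormFinder selection).
#' @export
normalize_ct <- function(ds, spec, treatment = NULL) {
  stopifnot(inherits(spec, "NormalizationSpec"))
  stability <- NULL
  out <- switch(spec$method,
    global_mean = normalize_global_mean(ds),
    modified_global_mean = normalize_modified_global_mean(ds),
    quantile = normalize_quantile(ds),
    norm_rank_invariant = normalize_rank_invariant(ds, "norm"),
    scale_rank_invariant = normalize_rank_invariant(ds, "scale"),
    deltact = {
      r <- normalize_deltact(ds, housekeepers = spec$housekeepers,
                             selector = spec$hk_selector,
                             treatment = treatment,
                             genorm_cutoff = spec$genorm_cutoff,
                             genorm_direction = spec$genorm_direction,
                             hk_count = spec$hk_count)
      stability <- r$stability
      r$dataset
    })
  structure(list(dataset = out, method = spec$method, stability = stability),
            class = "NormalizationResult")
}
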