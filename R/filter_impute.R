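#' Feature filtering specification
#'
#' @param max_missing_pct maximum admissible percentage of missing values
#'   per feature, in `[0, 100]`. The comparison is strict: a feature is
#'   removed when its missing percentage exceeds (not equals) the
#'   threshold, so a 25%-missing feature survives a setting of 25.
#' @param remove_names features to remove by name regardless of
#'   missingness.
#' @return A `FilterSpec` list.
#' @export
filter_spec <- function(max_missing_pct = 100, remove_names = character()) {
  stopifnot(is.numeric(max_missing_pct), length(max_missing_pct) == 1L)
  if (max_missing_pct < 0 || max_missing_pct > 100)
    stop("max_missing_pct must be in [0, 100]", call. = FALSE)
  structure(list(max_missing_pct = max_missing_pct,
                 remove_names = as.character(remove_names)),
            class = "FilterSpec")
}

#' Filter features by missingness and by name
#'
#' Removes features whose percentage of missing values strictly exceeds
#' `max_missing_pct`, and every feature named in `remove_names`. Original
#' order is preserved among survivors; removed features are reported in
#' the `"removed"` attribute (a data.frame with the reason).
#'
#' @param ds a [ct_dataset()].
#' @param spec a [filter_spec()].
#' @return The filtered dataset (possibly with zero features, with a
#'   warning).
#' @export
filter_features <- function(ds, spec = filter_spec()) {
  stopifnot(inherits(ds, "CtDataset"), inherits(spec, "FilterSpec"))
  miss_pct <- 100 * rowMeans(is.na(ds$ct))
  by_pct <- miss_pct > spec$max_missing_pct
  by_name <- ds$feature_names %in% spec$remove_names
  drop <- by_pct | by_name
  removed <- data.frame(
    feature = ds$feature_names[drop],
    missing_pct = miss_pct[drop],
    reason = ifelse(by_name[drop], "listed", "missingness"),
    stringsAsFactors = FALSE)
  out <- subset_features(ds, which(!drop))
  if (nrow(out$ct) == 0L)
    warning("all features removed by filtering", call. = FALSE)
  attr(out, "removed") <- removed
  out
}

#' Imputation specification
#'
#' @param method `"knn"`, `"mestdagh"` or `"cubic"`.
#' @param k number of neighbors (KNN only, default 10); must be smaller
#'   than the number of features.
#' @return An `ImputeSpec` list.
#' @export
impute_spec <- function(method = c("knn", "mestdagh", "cubic"), k = 10L) {
  method <- match.arg(method)
  k <- as.integer(k)
  if (method == "knn" && k <= 0L) stop("k must be positive", call. = FALSE)
  structure(list(method = method, k = k), class = "ImputeSpec")
}

#' Maximum-Ct-plus-one ("Mestdagh") imputation
#'
#' Replaces each missing Ct by the feature's maximum observed Ct across
#' samples plus one cycle — the low-abundance reading of missingness: an
#' undetected transcript is assumed at least one cycle less abundant than
#' its weakest detection. Features with no observed value at all fall back
#' to the dataset-wide maximum plus one. No upper clamp is applied.
#'
#' @param ds a [ct_dataset()].
#' @return The imputed dataset (no missing values remain).
#' @export
impute_mestdagh <- function(ds) {
  stopifnot(inherits(ds, "CtDataset"))
  x <- ds$ct
  if (all(is.na(x))) stop("entire dataset is missing", call. = FALSE)
  global_fill <- max(x, na.rm = TRUE) + 1
  row_max <- suppressWarnings(apply(x, 1L, max, na.rm = TRUE))
  fill <- ifelse(is.finite(row_max), row_max + 1, global_fill)
  idx <- which(is.na(x), arr.ind = TRUE)
  x[idx] <- fill[idx[, 1L]]
  set_ct(ds, x)
}

#' K-nearest-neighbors imputation
#'
#' For a feature g missing at sample s, candidate neighbors are the other
#' features observed at s; the distance to a candidate is the
#' root-mean-square difference over the samples where both features are
#' observed (Euclidean scaled by the shared-sample count so distances are
#' comparable across overlap sizes). The k nearest candidates contribute a
#' weighted mean of their values at s with weights 1/distance; if any
#' distance is zero, the zero-distance neighbors are averaged with equal
#' weights. With no qualifying neighbor the feature's own mean is used
#' (dataset mean for all-missing features).
#'
#' @param ds a [ct_dataset()].
#' @param spec an [impute_spec()] with `method = "knn"`.
#' @return The imputed dataset.
#' @export
impute_knn <- function(ds, spec = impute_spec("knn")) {
  stopifnot(inherits(ds, "CtDataset"))
  x <- ds$ct
  k <- spec$k
  if (k >= nrow(x))
    stop("k (", k, ") must be smaller than the number of features (",
         nrow(x), ")", call. = FALSE)
  if (all(is.na(x))) stop("entire dataset is missing", call. = FALSE)
  obs_mask <- !is.na(x)
  row_mean <- rowMeans(x, na.rm = TRUE)
  global_mean <- mean(x, na.rm = TRUE)
  out <- x
  for (g in which(apply(is.na(x), 1L, any))) {
    for (s in which(is.na(x[g, ]))) {
      cand <- which(obs_mask[, s])
      cand <- setdiff(cand, g)
      if (!length(cand)) {
        out[g, s] <- if (is.finite(row_mean[g])) row_mean[g] else global_mean
        next
      }
      shared <- obs_mask[cand, , drop = FALSE] &
        matrix(obs_mask[g, ], length(cand), ncol(x), byrow = TRUE)
      n_shared <- rowSums(shared)
      diff2 <- (x[cand, , drop = FALSE] -
                  matrix(x[g, ], length(cand), ncol(x), byrow = TRUE))^2
      diff2[!shared] <- 0
      d <- sqrt(rowSums(diff2, na.rm = TRUE) / pmax(n_shared, 1L))
      d[n_shared == 0L] <- NA
      usable <- which(!is.na(d))
      if (!length(usable)) {
        out[g, s] <- if (is.finite(row_mean[g])) row_mean[g] else global_mean
        next
      }
      nn <- usable[order(d[usable])][seq_len(min(k, length(usable)))]
      vals <- x[cand[nn], s]
      dd <- d[nn]
      out[g, s] <- if (any(dd == 0)) mean(vals[dd == 0]) else
        sum(vals / dd) / sum(1 / dd)
    }
  }
  set_ct(ds, out)
}

#' Cubic-spline imputation
#'
#' Applies the per-feature natural-spline fill of [spline_fill()] over the
#' sample index. Features with fewer than two observed values cannot
#' support a spline and fall back to the [impute_mestdagh()] rule; the
#' fallback rows are reported in the `"fallback_rows"` attribute.
#'
#' @param ds a [ct_dataset()].
#' @return The imputed dataset.
#' @export
impute_cubic <- function(ds) {
  stopifnot(inherits(ds, "CtDataset"))
  filled <- spline_fill(ds$ct)
  fallback <- attr(filled, "unfilled_rows")
  attr(filled, "unfilled_rows") <- NULL
  out <- set_ct(ds, filled)
  if (length(fallback)) {
    m <- impute_mestdagh(ds)
    out$ct[fallback, ] <- m$ct[fallback, ]
  }
  attr(out, "fallback_rows") <- fallback
  out
}

#' Impute missing Ct values
#'
#' Dispatcher over the three imputation methods.
#'
#' @param ds a [ct_dataset()].
#' @param spec an [impute_spec()].
#' @return The imputed dataset.
#' @export
impute_ct <- function(ds, spec = impute_spec()) {
  stopifnot(inherits(spec, "ImputeSpec"))
  switch(spec$method,
         knn = impute_knn(ds, spec),
         mestdagh = impute_mestdagh(ds),
         cubic = impute_cubic(ds))
}
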