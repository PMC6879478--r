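#' Ct dataset container
#'
#' A `CtDataset` holds the features x samples matrix of threshold-cycle (Ct)
#' values together with the per-well quality flags and the per-cell
#' reliability category ("OK", "Unreliable", "Undetermined"). Feature names
#' may be duplicated (replicated assays on a card); sample names must be
#' unique. A missing Ct (sentinel such as "Undetermined" in the source file,
#' or masked later by [mask_unreliable()]) is `NA`.
#'
#' @param ct numeric matrix, features in rows, samples in columns.
#' @param feature_names character vector, one per row (duplicates allowed).
#' @param sample_names character vector, one per column (unique).
#' @param flags character matrix of quality flags, same shape as `ct`
#'   (default: empty strings).
#' @param categories character matrix with values in
#'   `c("OK", "Unreliable", "Undetermined")`, same shape as `ct`. Default:
#'   "Undetermined" where `ct` is `NA` (sentinel in the source file), "OK"
#'   elsewhere.
#' @return An object of class `CtDataset`.
#' @export
ct_dataset <- function(ct, feature_names = rownames(ct),
                       sample_names = colnames(ct),
                       flags = NULL, categories = NULL) {
  ct <- as.matrix(ct)
  storage.mode(ct) <- "double"
  if (is.null(feature_names) || is.null(sample_names))
    stop("feature_names and sample_names are required", call. = FALSE)
  feature_names <- as.character(feature_names)
  sample_names <- as.character(sample_names)
  if (length(feature_names) != nrow(ct))
    stop("feature_names length does not match the number of rows", call. = FALSE)
  if (length(sample_names) != ncol(ct))
    stop("sample_names length does not match the number of columns", call. = FALSE)
  if (anyDuplicated(sample_names))
    stop("sample names must be unique", call. = FALSE)
  if (any(!nzchar(feature_names)))
    stop("feature names must be non-empty", call. = FALSE)
  if (is.null(flags)) {
    flags <- matrix("", nrow(ct), ncol(ct))
  } else {
    flags <- as.matrix(flags)
    storage.mode(flags) <- "character"
  }
  if (is.null(categories)) {
    categories <- matrix(ifelse(is.na(ct), "Undetermined", "OK"),
                         nrow(ct), ncol(ct))
  } else {
    categories <- as.matrix(categories)
    storage.mode(categories) <- "character"
  }
  if (!identical(dim(flags), dim(ct)) || !identical(dim(categories), dim(ct)))
    stop("flags and categories must have the same dimensions as ct", call. = FALSE)
  bad <- setdiff(unique(as.vector(categories)), CT_CATEGORIES)
  if (length(bad))
    stop("invalid category label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  dimnames(ct) <- dimnames(flags) <- dimnames(categories) <-
    list(feature_names, sample_names)
  structure(
    list(ct = ct, flags = flags, categories = categories,
         feature_names = feature_names, sample_names = sample_names),
    class = "CtDataset")
}

#' @export
dim.CtDataset <- function(x) dim(x$ct)

#' @export
print.CtDataset <- function(x, ...) {
  cat(sprintf("CtDataset: %d features x %d samples\n", nrow(x$ct), ncol(x$ct)))
  cat(sprintf("  missing Ct: %d (%.1f%%)\n", sum(is.na(x$ct)),
              100 * mean(is.na(x$ct))))
  tab <- table(factor(x$categories, levels = CT_CATEGORIES))
  cat("  categories:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# internal: replace the ct matrix, keeping names/flags/categories
set_ct <- function(ds, ct) {
  stopifnot(identical(dim(ct), dim(ds$ct)))
  dimnames(ct) <- dimnames(ds$ct)
  ds$ct <- ct
  ds
}

# internal: subset features by row index, preserving order
subset_features <- function(ds, idx) {
  ct_dataset(ds$ct[idx, , drop = FALSE],
             feature_names = ds$feature_names[idx],
             sample_names = ds$sample_names,
             flags = ds$flags[idx, , drop = FALSE],
             categories = ds$categories[idx, , drop = FALSE])
}

#' Treatment map
#'
#' Ordered assignment of samples to exactly two treatment groups. The
#' calibrator group (the reference of the relative-quantification ddCt
#' contrast) is the group of the first sample listed; the other group is
#' the target.
#'
#' @param sample_names character vector of sample (file) names, unique.
#' @param groups character vector of group labels, exactly two distinct.
#' @return An object of class `TreatmentMap` with elements `sample_names`,
#'   `groups`, `calibrator`, `target`.
#' @export
treatment_map <- function(sample_names, groups) {
  sample_names <- as.character(sample_names)
  groups <- as.character(groups)
  if (length(sample_names) != length(groups))
    stop("sample_names and groups must have equal length", call. = FALSE)
  if (anyDuplicated(sample_names))
    stop("duplicate sample names in treatment map: ",
         paste(unique(sample_names[duplicated(sample_names)]), collapse = ", "),
         call. = FALSE)
  lev <- unique(groups)
  if (length(lev) != 2L)
    stop("treatment map must contain exactly two distinct groups, found ",
         length(lev), ": ", paste(lev, collapse = ", "), call. = FALSE)
  structure(
    list(sample_names = sample_names, groups = groups,
         calibrator = groups[1L], target = setdiff(lev, groups[1L])),
    class = "TreatmentMap")
}

#' @export
print.TreatmentMap <- function(x, ...) {
  cat(sprintf("TreatmentMap: %d samples; calibrator=%s, target=%s\n",
              length(x$sample_names), x$calibrator, x$target))
  invisible(x)
}

# internal: sample indices of each group, calibrator first
group_indices <- function(tm, sample_names = tm$sample_names) {
  g <- tm$groups[match(sample_names, tm$sample_names)]
  list(calibrator = which(g == tm$calibrator),
       target = which(g == tm$target))
}
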