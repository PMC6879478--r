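#' Category settings
#'
#' Settings for the reliability categorization of Ct values: a user range
#' of acceptable cycles and an optional quality-flag check. Values outside
#' `[ct_min, ct_max]` become "Unreliable"; when `use_flags` is on, a cell
#' whose flag is in `fail_flag_values` becomes "Undetermined" (the flag
#' rule is applied after, and overrides, the range rule). The default
#' range `[0, Inf)` performs no range filtering.
#'
#' @param ct_min,ct_max range of Ct values (cycles) considered reliable.
#' @param use_flags check quality flags?
#' @param fail_flag_values flag values marking failed wells.
#' @return A `CategorySettings` list.
#' @export
category_settings <- function(ct_min = 0, ct_max = Inf, use_flags = FALSE,
                              fail_flag_values = "Failed") {
  stopifnot(is.numeric(ct_min), is.numeric(ct_max), length(ct_min) == 1L,
            length(ct_max) == 1L)
  if (!(ct_min < ct_max)) stop("ct_min must be < ct_max", call. = FALSE)
  structure(list(ct_min = ct_min, ct_max = ct_max,
                 use_flags = isTRUE(use_flags),
                 fail_flag_values = as.character(fail_flag_values)),
            class = "CategorySettings")
}

#' Assign reliability categories
#'
#' Recomputes the per-cell category from the Ct range and (optionally) the
#' quality flags. Cells that were missing in the source (sentinel) keep
#' their existing category; numeric cells outside the range become
#' "Unreliable"; failed-flag cells become "Undetermined" (overriding the
#' range label); everything else is "OK". Idempotent for fixed settings.
#'
#' @param ds a [ct_dataset()].
#' @param settings a [category_settings()].
#' @return The dataset with updated `categories`.
#' @export
assign_categories <- function(ds, settings = category_settings()) {
  stopifnot(inherits(ds, "CtDataset"), inherits(settings, "CategorySettings"))
  ct <- ds$ct
  cat_new <- ifelse(ct < settings$ct_min | ct > settings$ct_max,
                    "Unreliable", "OK")
  # missing cells (sentinel or already masked) keep their current label
  cat_new[is.na(ct)] <- ds$categories[is.na(ct)]
  if (settings$use_flags) {
    failed <- matrix(ds$flags %in% settings$fail_flag_values, nrow(ct))
    cat_new[failed] <- "Undetermined"
  }
  ds$categories[] <- cat_new
  ds
}

#' Mask non-OK Ct values as missing
#'
#' Replaces every Ct value whose category is "Unreliable" or "Undetermined"
#' with `NA`. Categories are retained so that downstream differential
#' expression can report per-group category summaries.
#'
#' @param ds a [ct_dataset()] with categories assigned.
#' @return The dataset with masked `ct`.
#' @export
mask_unreliable <- function(ds) {
  stopifnot(inherits(ds, "CtDataset"))
  ds$ct[ds$categories != "OK"] <- NA_real_
  ds
}
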