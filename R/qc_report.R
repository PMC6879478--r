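#' Per-feature coefficient of variation
#'
#' `CV_g = sd(values_g) / |mean(values_g)|` over the non-missing samples
#' of each feature, on the Ct scale. Features with fewer than 2 observed
#' values, or whose absolute mean falls below `eps` (possible after
#' centering normalizations), are dropped and reported in the
#' `"dropped"` attribute so the statistic stays finite.
#'
#' @param m numeric matrix, features x samples.
#' @param eps mean-magnitude guard (default 1e-8).
#' @return Named numeric vector of CVs with attribute `dropped`.
#' @export
cv_per_feature <- function(m, eps = 1e-8) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) rownames(m) <- paste0("feature", seq_len(nrow(m)))
  mu <- rowMeans(m, na.rm = TRUE)
  s <- apply(m, 1L, sd, na.rm = TRUE)
  n <- rowSums(!is.na(m))
  keep <- n >= 2L & is.finite(mu) & abs(mu) >= eps
  cv <- s[keep] / abs(mu[keep])
  names(cv) <- rownames(m)[keep]
  attr(cv, "dropped") <- rownames(m)[!keep]
  cv
}

#' Compare two CV distributions by ECDF and Kolmogorov-Smirnov test
#'
#' Two-sample two-sided KS: `D` is the supremum of the absolute
#' difference between the two empirical cumulative distribution functions;
#' the p-value is the asymptotic two-sample formula (feature counts are in
#' the hundreds for typical cards).
#'
#' @param cv_pre,cv_post numeric vectors (e.g. CVs before and after
#'   normalization).
#' @return List with `ks_D`, `ks_p`, and `ecdf_pre` / `ecdf_post` step
#'   curves (data.frames of sorted `value` and cumulative `fraction`).
#' @export
ecdf_compare <- function(cv_pre, cv_post) {
  cv_pre <- cv_pre[is.finite(cv_pre)]
  cv_post <- cv_post[is.finite(cv_post)]
  if (!length(cv_pre) || !length(cv_post))
    stop("empty CV vector", call. = FALSE)
  ks <- suppressWarnings(ks.test(cv_pre, cv_post, exact = FALSE))
  curve <- function(v) {
    v <- sort(v)
    data.frame(value = v, fraction = seq_along(v) / length(v))
  }
  list(ks_D = unname(ks$statistic), ks_p = ks$p.value,
       ecdf_pre = curve(cv_pre), ecdf_post = curve(cv_post))
}

five_number_table <- function(ds) {
  fn <- vapply(seq_len(ncol(ds$ct)), function(j)
    fivenum(ds$ct[!is.na(ds$ct[, j]), j]), numeric(5L))
  out <- as.data.frame(t(fn))
  names(out) <- c("min", "q1", "median", "q3", "max")
  cbind(sample = ds$sample_names, out, stringsAsFactors = FALSE)
}

#' Build the QC report
#'
#' Per-sample five-number summaries of the Ct distributions before and
#' after normalization, per-feature CV vectors on both matrices, and the
#' KS comparison of the two CV distributions. "Before" is the dataset
#' after categorization and masking; "after" is the normalized dataset.
#'
#' @param ds_pre dataset after categorization/masking.
#' @param ds_post normalized dataset.
#' @return A `QCReport` list.
#' @export
qc_report <- function(ds_pre, ds_post) {
  cv_pre <- cv_per_feature(ds_pre$ct)
  cv_post <- cv_per_feature(ds_post$ct)
  cmp <- ecdf_compare(cv_pre, cv_post)
  structure(list(summary_pre = five_number_table(ds_pre),
                 summary_post = five_number_table(ds_post),
                 cv_pre = cv_pre, cv_post = cv_post,
                 ks_D = cmp$ks_D, ks_p = cmp$ks_p,
                 ecdf_pre = cmp$ecdf_pre, ecdf_post = cmp$ecdf_post),
            class = "QCReport")
}

#' Render the per-sample Ct boxplots
#'
#' One box per sample, in treatment-file order, missing values skipped.
#'
#' @param ds a [ct_dataset()].
#' @param path output PNG path.
#' @param main plot title.
#' @return `path`, invisibly.
#' @export
render_boxplots <- function(ds, path, main = "Ct distribution per sample") {
  png(path, width = 1000, height = 600)
  on.exit(dev.off())
  cols <- lapply(seq_len(ncol(ds$ct)), function(j)
    ds$ct[!is.na(ds$ct[, j]), j])
  names(cols) <- ds$sample_names
  boxplot(cols, las = 2, main = main, ylab = "Ct (cycles)",
          col = "steelblue")
  invisible(path)
}

#' Render the CV ECDF comparison plot
#'
#' Two ECDF curves (pre- and post-normalization CVs) with the KS p-value
#' in the title.
#'
#' @param report a [qc_report()].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
render_ecdf <- function(report, path) {
  png(path, width = 800, height = 600)
  on.exit(dev.off())
  xlim <- range(report$ecdf_pre$value, report$ecdf_post$value)
  plot(report$ecdf_pre$value, report$ecdf_pre$fraction, type = "s",
       col = "blue", lwd = 2, xlim = xlim, ylim = c(0, 1),
       xlab = "coefficient of variation", ylab = "cumulative fraction",
       main = sprintf("CV before/after normalization (KS p = %.3g)",
                      report$ks_p))
  lines(report$ecdf_post$value, report$ecdf_post$fraction, type = "s",
        col = "darkgreen", lwd = 2)
  legend("bottomright", legend = c("pre-normalization", "post-normalization"),
         col = c("blue", "darkgreen"), lwd = 2, bty = "n")
  invisible(path)
}

#' Write the QC summary sidecar tables
#'
#' Tab-separated dumps of the per-sample five-number summaries and the KS
#' result, for programmatic inspection alongside the PNGs.
#'
#' @param report a [qc_report()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_qc_summary <- function(report, path) {
  pre <- cbind(stage = "pre", report$summary_pre)
  post <- cbind(stage = "post", report$summary_post)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# KS D = %.6g, p = %.6g", report$ks_D, report$ks_p),
             con)
  write.table(rbind(pre, post), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
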