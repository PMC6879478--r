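#' Pipeline configuration
#'
#' Bundles every stage's settings for an end-to-end run. Inputs are either
#' a directory of report files (all samples named in the treatment file
#' must be present) or an explicit named vector of paths.
#'
#' @param input paths to the per-sample report files (named by sample
#'   name) or a single directory containing files named as in the
#'   treatment file.
#' @param treatment_path path to the treatment file.
#' @param output_dir directory for the seven outputs and the run log.
#' @param dialect report dialect (see [ct_dialects()]).
#' @param categories a [category_settings()].
#' @param normalization a [normalization_spec()].
#' @param filter a [filter_spec()].
#' @param imputation an [impute_spec()].
#' @param de a [de_spec()].
#' @param seed seed forwarded to stochastic stages (rank product) unless
#'   the DE spec carries its own.
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(input, treatment_path, output_dir,
                            dialect = "plain",
                            categories = category_settings(),
                            normalization = normalization_spec("global_mean"),
                            filter = filter_spec(),
                            imputation = impute_spec("knn"),
                            de = de_spec("ttest"), seed = 1L) {
  structure(list(input = input, treatment_path = treatment_path,
                 output_dir = output_dir, dialect = dialect,
                 categories = categories, normalization = normalization,
                 filter = filter, imputation = imputation, de = de,
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

pipeline_stage <- function(name, expr, log) {
  log(sprintf("stage: %s", name))
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the five-stage pipeline
#'
#' Executes parse -> categorize/mask -> normalize -> filter -> impute ->
#' differential expression and writes the seven standard outputs plus a
#' run log into `output_dir`:
#'
#' 1. `raw_ct.tsv` — raw Ct matrix;
#' 2. `boxplot_raw.png` — per-sample Ct distributions after
#'    categorization/masking;
#' 3. `normalized_ct.tsv` — normalized Ct matrix;
#' 4. `cv_ecdf.png` — CV ECDFs before/after normalization with the KS
#'    p-value;
#' 5. `boxplot_normalized.png` — per-sample normalized distributions;
#' 6. `imputed_ct.tsv` — filtered and imputed matrix;
#' 7. `de_results.tsv` — differential expression table (headers only when
#'    the DE method is `"none"`).
#'
#' A failing stage aborts with the stage name; outputs already written are
#' kept. Identical configuration and seed give byte-identical tabular
#' outputs.
#'
#' @param cfg a [pipeline_config()].
#' @return Invisibly, a manifest list: `outputs` (named paths), `log`
#'   (path), `de_table`, `qc`, `stability`, `removed_features`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$output_dir, "run_log.txt")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))
  log <- function(...) writeLines(paste0(...), log_con)
  log("ctpipe run")
  log(sprintf("seed: %d", cfg$seed))
  log(sprintf("dialect: %s", if (inherits(cfg$dialect, "FormatDialect"))
    cfg$dialect$name else cfg$dialect))
  log(sprintf("normalization: %s", cfg$normalization$method))
  log(sprintf("ct range: [%g, %g], use_flags: %s", cfg$categories$ct_min,
              cfg$categories$ct_max, cfg$categories$use_flags))
  log(sprintf("max missing pct: %g", cfg$filter$max_missing_pct))
  log(sprintf("imputation: %s", cfg$imputation$method))
  log(sprintf("de method: %s (adjust %s, alternative %s)", cfg$de$method,
              cfg$de$adjust, cfg$de$alternative))

  tm <- pipeline_stage("parse_treatment",
                       parse_treatment_file(cfg$treatment_path), log)
  paths <- if (length(cfg$input) == 1L && dir.exists(cfg$input))
    setNames(file.path(cfg$input, tm$sample_names), tm$sample_names) else
      cfg$input
  if (is.null(names(paths))) names(paths) <- basename(paths)
  records <- pipeline_stage("parse_reports", lapply(paths, parse_ct_file,
                                                    dialect = cfg$dialect),
                            log)
  ds <- pipeline_stage("assemble", assemble_dataset(records, tm), log)
  log(sprintf("dataset: %d features x %d samples", nrow(ds$ct), ncol(ds$ct)))

  ds <- pipeline_stage("categorize", assign_categories(ds, cfg$categories),
                       log)
  masked <- pipeline_stage("mask", mask_unreliable(ds), log)

  out <- list(
    raw_ct = file.path(cfg$output_dir, "raw_ct.tsv"),
    boxplot_raw = file.path(cfg$output_dir, "boxplot_raw.png"),
    normalized_ct = file.path(cfg$output_dir, "normalized_ct.tsv"),
    cv_ecdf = file.path(cfg$output_dir, "cv_ecdf.png"),
    boxplot_normalized = file.path(cfg$output_dir, "boxplot_normalized.png"),
    imputed_ct = file.path(cfg$output_dir, "imputed_ct.tsv"),
    de_results = file.path(cfg$output_dir, "de_results.tsv"))

  pipeline_stage("write_raw", write_ct_table(ds, out$raw_ct), log)
  pipeline_stage("boxplot_raw",
                 render_boxplots(masked, out$boxplot_raw,
                                 "Ct per sample (after categorization)"), log)

  norm <- pipeline_stage("normalize",
                         normalize_ct(masked, cfg$normalization, tm), log)
  if (!is.null(norm$stability))
    log(sprintf("selected housekeepers: %s",
                paste(norm$stability$selected, collapse = ", ")))
  pipeline_stage("write_normalized",
                 write_ct_table(norm$dataset, out$normalized_ct), log)
  qc <- pipeline_stage("qc", qc_report(masked, norm$dataset), log)
  log(sprintf("KS D = %.6g, p = %.6g", qc$ks_D, qc$ks_p))
  pipeline_stage("cv_ecdf", render_ecdf(qc, out$cv_ecdf), log)
  pipeline_stage("boxplot_normalized",
                 render_boxplots(norm$dataset, out$boxplot_normalized,
                                 "Normalized Ct per sample"), log)
  pipeline_stage("qc_sidecar",
                 write_qc_summary(qc, file.path(cfg$output_dir,
                                                "qc_summary.tsv")), log)

  filtered <- pipeline_stage("filter", filter_features(norm$dataset,
                                                       cfg$filter), log)
  removed <- attr(filtered, "removed")
  log(sprintf("removed features: %d", nrow(removed)))
  if (nrow(removed))
    log(paste("  -", removed$feature, sprintf("(%s)", removed$reason),
              collapse = "\n"))
  imputed <- pipeline_stage("impute", impute_ct(filtered, cfg$imputation),
                            log)
  pipeline_stage("write_imputed", write_ct_table(imputed, out$imputed_ct),
                 log)

  de_cfg <- cfg$de
  if (is.null(de_cfg$seed)) de_cfg$seed <- cfg$seed
  de_tab <- pipeline_stage("diffexp", run_de(imputed, tm, de_cfg), log)
  if (de_cfg$method == "none") log("de: NONE (no test performed)")
  pipeline_stage("write_de", write_de_table(de_tab, out$de_results), log)
  log("done")

  invisible(list(outputs = out, log = log_path, de_table = de_tab, qc = qc,
                 stability = norm$stability, removed_features = removed))
}
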