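#' Ct report file dialects
#'
#' Vendor exports of RT-qPCR runs are tab-separated text reports that differ
#' in header layout and column names. A dialect describes how to locate the
#' data block and which columns carry the feature name, the Ct/Cq value, the
#' quality flag and (optionally) the well position. Files must use "." as
#' the decimal separator.
#'
#' `ct_dialect()` builds a custom dialect; `ct_dialects()` returns the
#' shipped registry. SDS (v2.3/2.4 exports), EDS exports and Plain
#' (headerless `feature<TAB>Ct[<TAB>flag]`) are exercised by the test
#' suite; the OpenArray, LightCycler, CFX and BioMark entries are
#' templates with commonly seen column names that users can adjust with
#' `ct_dialect()` because vendor layouts vary between software versions.
#'
#' @param name dialect name.
#' @param feature_cols candidate column names holding the feature name
#'   (first match wins). `NULL` for headerless positional files.
#' @param ct_cols candidate column names holding the Ct value.
#' @param flag_cols candidate column names holding the quality flag.
#' @param position_cols candidate column names holding the well position.
#' @param sentinels values (case-insensitive) treated as missing Ct.
#' @param headerless if `TRUE` the file has no header; columns are
#'   positional: feature, Ct, optional flag.
#' @return A `FormatDialect` list.
#' @export
ct_dialect <- function(name, feature_cols = NULL, ct_cols = NULL,
                       flag_cols = character(), position_cols = character(),
                       sentinels = c("Undetermined", "No Ct", "NA", ""),
                       headerless = FALSE) {
  if (!headerless && (is.null(feature_cols) || is.null(ct_cols)))
    stop("headered dialects need feature_cols and ct_cols", call. = FALSE)
  structure(list(name = name, feature_cols = feature_cols, ct_cols = ct_cols,
                 flag_cols = flag_cols, position_cols = position_cols,
                 sentinels = tolower(sentinels), headerless = headerless),
            class = "FormatDialect")
}

#' @rdname ct_dialect
#' @export
ct_dialects <- function() {
  list(
    plain = ct_dialect("plain", headerless = TRUE),
    sds = ct_dialect("sds",
                     feature_cols = c("Detector", "Detector Name"),
                     ct_cols = c("Ct", "Avg Ct", "Cq"),
                     flag_cols = c("Flag", "Flags", "Omit"),
                     position_cols = c("Well", "Position")),
    eds = ct_dialect("eds",
                     feature_cols = c("Target Name", "Target"),
                     ct_cols = c("CT", "Ct", "Cq"),
                     flag_cols = c("Status", "Flag"),
                     position_cols = "Well"),
    # templates: adjust column names to the local export with ct_dialect()
    openarray = ct_dialect("openarray",
                           feature_cols = c("Assay Name", "Assay ID"),
                           ct_cols = c("Ct", "Crt"),
                           flag_cols = "Flags",
                           position_cols = "Well"),
    lightcycler = ct_dialect("lightcycler",
                             feature_cols = "Name",
                             ct_cols = c("Cp", "Cq"),
                             flag_cols = "Status",
                             position_cols = "Pos"),
    cfx = ct_dialect("cfx",
                     feature_cols = "Target",
                     ct_cols = "Cq",
                     flag_cols = "Call",
                     position_cols = "Well"),
    biomark = ct_dialect("biomark",
                         feature_cols = "Name",
                         ct_cols = "Value",
                         flag_cols = "Call",
                         position_cols = "ID")
  )
}

resolve_dialect <- function(dialect) {
  if (inherits(dialect, "FormatDialect")) return(dialect)
  reg <- ct_dialects()
  key <- tolower(as.character(dialect))
  if (!key %in% names(reg))
    stop("unknown dialect '", dialect, "'; shipped dialects: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  reg[[key]]
}

read_tsv_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  sub("\r$", "", lines)
}

# parse a Ct field: numeric, or NA for a sentinel; anything else is an error
parse_ct_value <- function(x, sentinels, path, row) {
  x <- trimws(x)
  out <- suppressWarnings(as.numeric(x))
  bad <- is.na(out) & !(tolower(x) %in% sentinels)
  if (any(bad))
    stop(sprintf(
      "%s: non-numeric, non-sentinel Ct value %s at data row %d (decimal separator must be '.')",
      path, dQuote(x[bad][1L]), row[bad][1L]), call. = FALSE)
  out
}

#' Parse one Ct report file
#'
#' Reads a tab-separated Ct report in the given dialect and returns one
#' record per data row, in file order. Sentinel Ct values (e.g.
#' "Undetermined") become `NA`; every other Ct field must be numeric with a
#' "." decimal separator.
#'
#' @param path path to a tab-separated report file.
#' @param dialect a `FormatDialect` or the name of a shipped dialect
#'   (see [ct_dialects()]).
#' @return A data.frame with columns `feature_name`, `ct`, `flag`,
#'   `position`, one row per data row in file order.
#' @export
parse_ct_file <- function(path, dialect = "plain") {
  d <- resolve_dialect(dialect)
  lines <- read_tsv_lines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  if (!length(lines)) stop(path, ": empty file", call. = FALSE)
  cells <- strsplit(lines, "\t", fixed = TRUE)

  if (d$headerless) {
    first <- trimws(cells[[1L]])
    # tolerate a single header line naming the columns
    skip <- length(first) >= 2L && tolower(first[2L]) %in% c("ct", "cq")
    rows <- cells[seq.int(1L + skip, length(cells))]
    n <- length(rows)
    feat <- ct_raw <- flag <- character(n)
    for (i in seq_len(n)) {
      f <- trimws(rows[[i]])
      if (length(f) < 2L)
        stop(sprintf("%s: data row %d has fewer than 2 columns", path, i),
             call. = FALSE)
      feat[i] <- f[1L]
      ct_raw[i] <- f[2L]
      flag[i] <- if (length(f) >= 3L) f[3L] else ""
    }
    ct <- parse_ct_value(ct_raw, d$sentinels, path, seq_len(n))
    pos <- rep(NA_character_, n)
  } else {
    # locate the header row: first line containing a feature column and a
    # Ct column (vendor exports carry a free-text preamble above it)
    is_header <- vapply(cells, function(f) {
      f <- trimws(f)
      any(f %in% d$feature_cols) && any(f %in% d$ct_cols)
    }, logical(1L))
    if (!any(is_header))
      stop(path, ": data block not found for dialect '", d$name,
           "' (no header row with columns ",
           paste(d$feature_cols, collapse = "/"), " and ",
           paste(d$ct_cols, collapse = "/"), ")", call. = FALSE)
    h <- which(is_header)[1L]
    header <- trimws(cells[[h]])
    pick <- function(cands) {
      j <- which(header %in% cands)
      if (length(j)) j[1L] else NA_integer_
    }
    jf <- pick(d$feature_cols); jc <- pick(d$ct_cols)
    jfl <- pick(d$flag_cols); jp <- pick(d$position_cols)
    rows <- cells[seq.int(h + 1L, length(cells))]
    rows <- rows[vapply(rows, function(f) any(nzchar(trimws(f))), logical(1L))]
    n <- length(rows)
    if (!n) stop(path, ": no data rows below the header", call. = FALSE)
    get <- function(f, j, default = "")
      if (!is.na(j) && length(f) >= j) trimws(f[j]) else default
    feat <- vapply(rows, get, "", j = jf)
    ct_raw <- vapply(rows, get, "", j = jc)
    flag <- vapply(rows, get, "", j = jfl)
    pos <- if (is.na(jp)) rep(NA_character_, n) else vapply(rows, get, "", j = jp)
    ct <- parse_ct_value(ct_raw, d$sentinels, path, seq_len(n))
  }
  if (any(!nzchar(feat)))
    stop(sprintf("%s: empty feature name at data row %d", path,
                 which(!nzchar(feat))[1L]), call. = FALSE)
  data.frame(feature_name = feat, ct = ct, flag = flag, position = pos,
             stringsAsFactors = FALSE)
}

#' Parse the treatment file
#'
#' The treatment file is a two-column tab-separated table with header
#' `SampleName<TAB>Treatment`, listing the report file names in analysis
#' order and the group of each sample. Exactly two distinct groups are
#' required; the calibrator group is that of the first row.
#'
#' @param path path to the treatment file.
#' @return A [treatment_map()].
#' @export
parse_treatment_file <- function(path) {
  lines <- read_tsv_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop(path, ": treatment file needs a header and at least one sample",
         call. = FALSE)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- trimws(cells[[1L]])
  if (length(header) != 2L || !identical(header, c("SampleName", "Treatment")))
    stop(path, ": treatment file must have exactly the two columns ",
         "'SampleName' and 'Treatment'", call. = FALSE)
  rows <- cells[-1L]
  bad <- which(lengths(rows) != 2L)
  if (length(bad))
    stop(sprintf("%s: row %d does not have exactly 2 columns", path,
                 bad[1L] + 1L), call. = FALSE)
  m <- do.call(rbind, rows)
  treatment_map(trimws(m[, 1L]), trimws(m[, 2L]))
}

#' Assemble the per-sample records into a Ct dataset
#'
#' Stacks the parsed per-sample record lists into a features x samples
#' dataset, with sample columns in treatment-file order. All samples must
#' report the identical ordered feature list (the plate layout); ragged
#' inputs are an error that names the differing features. Default
#' categories follow the sentinel rule: "Undetermined" where the source
#' value was missing, "OK" elsewhere.
#'
#' @param per_sample_records named list (sample name -> data.frame from
#'   [parse_ct_file()]).
#' @param treatment a [treatment_map()].
#' @return A [ct_dataset()].
#' @export
assemble_dataset <- function(per_sample_records, treatment) {
  miss <- setdiff(treatment$sample_names, names(per_sample_records))
  if (length(miss))
    stop("sample(s) in the treatment file without a report: ",
         paste(miss, collapse = ", "), call. = FALSE)
  recs <- per_sample_records[treatment$sample_names]
  feats <- recs[[1L]]$feature_name
  for (s in treatment$sample_names[-1L]) {
    f <- recs[[s]]$feature_name
    if (!identical(f, feats)) {
      d <- union(setdiff(f, feats), setdiff(feats, f))
      detail <- if (length(d))
        paste0("; differing features: ", paste(head(d, 10L), collapse = ", "))
      else "; same features, different order or multiplicity"
      stop("feature lists disagree across samples (sample ", s, detail, ")",
           call. = FALSE)
    }
  }
  ct <- vapply(recs, function(r) r$ct, numeric(length(feats)))
  flags <- vapply(recs, function(r) r$flag, character(length(feats)))
  ct <- matrix(ct, nrow = length(feats))
  flags <- matrix(flags, nrow = length(feats))
  ct_dataset(ct, feature_names = feats, sample_names = treatment$sample_names,
             flags = flags)
}

# shortest decimal representation that parses back to the identical double
format_ct_value <- function(x) {
  out <- ifelse(is.na(x), "NA", format(x, trim = TRUE, digits = 15,
                                       scientific = FALSE))
  redo <- !is.na(x) & suppressWarnings(as.numeric(out)) != x
  out[redo] <- sprintf("%.17g", x[redo])
  out
}

#' Write / read a Ct value table
#'
#' `write_ct_table()` writes the Ct matrix as a tab-separated grid with
#' features as rows and samples as columns, `NA` for missing, "." decimal,
#' at full precision (values round-trip bit-identically through
#' `read_ct_table()`).
#'
#' @param ds a [ct_dataset()].
#' @param path output (or input) path.
#' @return `write_ct_table()` returns `path` invisibly; `read_ct_table()`
#'   returns a [ct_dataset()] (flags empty, categories by the sentinel
#'   rule).
#' @export
write_ct_table <- function(ds, path) {
  body <- apply(ds$ct, 2L, format_ct_value)
  body <- matrix(body, nrow = nrow(ds$ct))
  lines <- c(paste(c("feature", ds$sample_names), collapse = "\t"),
             paste(ds$feature_names, apply(body, 1L, paste, collapse = "\t"),
                   sep = "\t"))
  tryCatch(writeLines(lines, path),
           error = function(e) stop("cannot write ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' @rdname write_ct_table
#' @export
read_ct_table <- function(path) {
  lines <- read_tsv_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  cells <- strsplit(lines, "\t", fixed = TRUE)
  samples <- cells[[1L]][-1L]
  rows <- cells[-1L]
  feats <- vapply(rows, `[`, "", 1L)
  ct <- t(vapply(rows, function(f)
    parse_ct_value(f[-1L], c("na", ""), path, NA_integer_),
    numeric(length(samples))))
  ct <- matrix(ct, ncol = length(samples))
  ct_dataset(ct, feature_names = feats, sample_names = samples)
}
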