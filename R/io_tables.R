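# CSV readers and writers for the pipeline's tables. Dialect is explicit:
# comma-separated UTF-8 with "." decimals and a mandatory header by default;
# `sep` admits ";" and tab. Numerics are written with 15 significant digits so
# write -> read round-trips to at least 12 significant digits.

.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.15g", v)
  }, character(1))
  out
}

# write a data frame as CSV, quoting the named text columns (identifiers and
# display names may contain the separator, e.g. "fructose-1,6-bisphosphate")
.write_csv <- function(df, path, sep = ",", quote_cols = character(0)) {
  qi <- which(names(df) %in% quote_cols)
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     quote = if (length(qi)) qi else FALSE,
                     fileEncoding = "UTF-8")
}

.text_cols <- function(df) names(df)[vapply(df, is.character, logical(1))]

.read_csv_raw <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.csv(path, sep = sep, check.names = FALSE,
                  stringsAsFactors = FALSE, colClasses = "character",
                  na.strings = NULL, fileEncoding = "UTF-8")
}

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s: missing mandatory column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
}

# convert a character column to numeric, reporting the 1-based data row of the
# first unparseable non-empty cell
.to_numeric <- function(x, column, what) {
  empty <- !nzchar(trimws(x))
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !empty)
  if (length(bad))
    stop(sprintf("%s: non-numeric value '%s' in column '%s' at row %d",
                 what, x[bad[1]], column, bad[1]), call. = FALSE)
  out[empty] <- NA_real_
  out
}

#' Read a feature-intensity table
#'
#' Reads a features-by-samples CSV with mandatory columns `feature_id`, `mz`,
#' `rt` followed by one intensity column per sample. Empty intensity cells are
#' recorded as missing (`NA`), never as zero: downstream replicate counts use
#' present values only.
#'
#' @param path CSV file path.
#' @param sep Field separator: `","` (default), `";"` or `"\t"`.
#' @param rt_unit `"seconds"` (default) or `"minutes"`; minutes are converted
#'   to seconds on load.
#' @return A `feature_table`: a data frame with columns `feature_id`, `mz`,
#'   `rt` and one numeric column per sample.
#' @export
read_feature_table <- function(path, sep = ",", rt_unit = c("seconds", "minutes")) {
  rt_unit <- match.arg(rt_unit)
  df <- .read_csv_raw(path, sep)
  .require_columns(df, c("feature_id", "mz", "rt"), "feature table")
  sample_ids <- setdiff(names(df), c("feature_id", "mz", "rt"))
  out <- data.frame(feature_id = df$feature_id, stringsAsFactors = FALSE)
  out$mz <- .to_numeric(df$mz, "mz", "feature table")
  out$rt <- .to_numeric(df$rt, "rt", "feature table")
  if (rt_unit == "minutes") out$rt <- out$rt * 60
  for (s in sample_ids) out[[s]] <- .to_numeric(df[[s]], s, "feature table")
  feature_table(out)
}

#' Construct and validate a feature table
#'
#' @param df Data frame with `feature_id`, `mz`, `rt` and sample columns.
#' @return Validated `feature_table`.
#' @export
feature_table <- function(df) {
  stopifnot(is.data.frame(df))
  .require_columns(df, c("feature_id", "mz", "rt"), "feature table")
  dup <- unique(df$feature_id[duplicated(df$feature_id)])
  if (length(dup))
    stop("feature table: duplicated feature_id: ",
         paste(dup, collapse = ", "), call. = FALSE)
  if (any(!is.finite(df$mz)) || any(df$mz <= 0))
    stop("feature table: mz must be finite and > 0", call. = FALSE)
  if (any(!is.finite(df$rt)) || any(df$rt < 0))
    stop("feature table: rt must be finite and >= 0", call. = FALSE)
  for (s in sample_ids(df)) {
    v <- df[[s]]
    if (!is.numeric(v)) stop("feature table: intensity column '", s,
                             "' is not numeric", call. = FALSE)
    if (any(v < 0, na.rm = TRUE))
      stop("feature table: negative intensity in column '", s, "'",
           call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("feature_table", "data.frame")
  df
}

#' Sample columns of a feature table
#' @param features A `feature_table` (or compatible data frame).
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(features) {
  setdiff(names(features), c("feature_id", "mz", "rt"))
}

#' Write a feature table
#' @param features A `feature_table`.
#' @param path Output CSV path.
#' @param sep Field separator.
#' @export
write_feature_table <- function(features, path, sep = ",") {
  df <- as.data.frame(features)
  out <- data.frame(feature_id = df$feature_id, mz = .fmt_num(df$mz),
                    rt = .fmt_num(df$rt), stringsAsFactors = FALSE,
                    check.names = FALSE)
  for (s in sample_ids(df)) out[[s]] <- .fmt_num(df[[s]])
  .write_csv(out, path, sep, quote_cols = "feature_id")
  invisible(path)
}

#' Read a sample sheet
#'
#' Reads sample metadata mapping each sample to an experiment, a condition, a
#' tracer state (`labeled` or `unlabeled`) and a replicate index. A sheet with
#' no unlabeled sample loads with a warning (attribute `no_unlabeled`); the
#' hard error is deferred to the detection step, which needs the unlabeled
#' counterpart.
#'
#' @param path CSV with columns `sample_id`, `experiment`, `condition`,
#'   `tracer_state`, `replicate`.
#' @param sep Field separator.
#' @return A `sample_sheet` data frame.
#' @export
read_sample_sheet <- function(path, sep = ",") {
  df <- .read_csv_raw(path, sep)
  .require_columns(df, c("sample_id", "experiment", "condition",
                         "tracer_state", "replicate"), "sample sheet")
  df$replicate <- .to_numeric(df$replicate, "replicate", "sample sheet")
  sample_sheet(df)
}

#' Construct and validate a sample sheet
#' @param df Data frame with the sample-sheet columns.
#' @return Validated `sample_sheet`.
#' @export
sample_sheet <- function(df) {
  .require_columns(df, c("sample_id", "experiment", "condition",
                         "tracer_state", "replicate"), "sample sheet")
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup))
    stop("sample sheet: duplicated sample_id: ", paste(dup, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(df$tracer_state), c("labeled", "unlabeled"))
  if (length(bad))
    stop("sample sheet: tracer_state must be 'labeled' or 'unlabeled', got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (any(!is.finite(df$replicate)) || any(df$replicate < 1) ||
      any(df$replicate != round(df$replicate)))
    stop("sample sheet: replicate must be a positive integer", call. = FALSE)
  df$replicate <- as.integer(df$replicate)
  rownames(df) <- NULL
  class(df) <- c("sample_sheet", "data.frame")
  if (!any(df$tracer_state == "unlabeled")) {
    warning("sample sheet contains no unlabeled sample; ",
            "MID correction will not be possible", call. = FALSE)
    attr(df, "no_unlabeled") <- TRUE
  }
  df
}

#' Write a sample sheet
#' @param samples A `sample_sheet`.
#' @param path Output CSV path.
#' @param sep Field separator.
#' @export
write_sample_sheet <- function(samples, path, sep = ",") {
  df <- as.data.frame(samples)
  .write_csv(df, path, sep, quote_cols = .text_cols(df))
  invisible(path)
}

#' Read an MID table
#'
#' Reads a per-node, per-condition MID table with fraction columns `M0..Mk`
#' (variable k), optional `SD_0..SD_k`, and optional `display_name`,
#' `enrichment`, `quantification`, `quantification_sd`, `residual`,
#' `annotated` columns. Fraction vectors whose sum deviates from 1 by at most
#' 2% are renormalized (third-party files are typically rounded); larger
#' deviations are rejected with the row id. Negative fractions are rejected.
#'
#' @param path CSV file path.
#' @param sep Field separator.
#' @return A `mid_table` data frame.
#' @export
read_mid_table <- function(path, sep = ",") {
  df <- .read_csv_raw(path, sep)
  .require_columns(df, c("node_id", "condition", "experiment"), "MID table")
  mcols <- grep("^M[0-9]+$", names(df), value = TRUE)
  if (!length(mcols)) stop("MID table: no M0..Mk fraction columns found",
                           call. = FALSE)
  ord <- order(as.integer(sub("^M", "", mcols)))
  mcols <- mcols[ord]
  sdcols <- grep("^SD_[0-9]+$", names(df), value = TRUE)
  sdcols <- sdcols[order(as.integer(sub("^SD_", "", sdcols)))]
  for (cn in c(mcols, sdcols,
               intersect(c("enrichment", "quantification",
                           "quantification_sd", "residual"), names(df))))
    df[[cn]] <- .to_numeric(df[[cn]], cn, "MID table")
  frac <- as.matrix(df[, mcols, drop = FALSE])
  frac[is.na(frac)] <- 0
  if (any(frac < 0)) {
    row <- which(apply(frac < 0, 1, any))[1]
    stop("MID table: negative fraction in row '", df$node_id[row], "'",
         call. = FALSE)
  }
  sums <- rowSums(frac)
  off <- abs(sums - 1) > 0.02
  if (any(off))
    stop("MID table: fractions of node '", df$node_id[which(off)[1]],
         "' sum to ", format(sums[which(off)[1]]),
         " (more than 2% from 1)", call. = FALSE)
  scale <- 1 / sums
  frac <- frac * scale
  df[, mcols] <- frac
  if (length(sdcols)) {
    if (length(sdcols) != length(mcols))
      stop("MID table: SD_ column count does not match M column count",
           call. = FALSE)
    sds <- as.matrix(df[, sdcols, drop = FALSE])
    sds[is.na(sds)] <- 0
    if (any(sds < 0)) stop("MID table: negative fraction SD", call. = FALSE)
    df[, sdcols] <- sds * scale
  }
  df$enrichment <- 1 - frac[, 1]  # invariant: recompute after renormalization
  if (is.null(df$display_name)) df$display_name <- df$node_id
  if (is.null(df$annotated)) {
    df$annotated <- nzchar(df$display_name) & df$display_name != df$node_id
  } else {
    df$annotated <- tolower(as.character(df$annotated)) %in%
      c("true", "t", "1", "yes")
  }
  if (is.null(df$quantification)) df$quantification <- NA_real_
  mid_table(df)
}

#' Construct and validate an MID table
#' @param df Data frame with `node_id`, `condition`, `experiment` and
#'   `M0..Mk` columns.
#' @return Validated `mid_table`.
#' @export
mid_table <- function(df) {
  .require_columns(df, c("node_id", "condition", "experiment"), "MID table")
  mcols <- mid_fraction_columns(df)
  frac <- as.matrix(df[, mcols, drop = FALSE])
  if (any(frac < 0)) stop("MID table: negative fraction", call. = FALSE)
  if (any(abs(rowSums(frac) - 1) > 1e-6))
    stop("MID table: fraction vectors must sum to 1 within 1e-6",
         call. = FALSE)
  if (!is.null(df$enrichment) &&
      any(abs(df$enrichment - (1 - frac[, 1])) > 1e-9))
    stop("MID table: enrichment must equal 1 - M0", call. = FALSE)
  rownames(df) <- NULL
  class(df) <- c("mid_table", "data.frame")
  df
}

#' Fraction column names of an MID table
#' @param mids A `mid_table`.
#' @return Character vector `M0`, `M1`, ... in order.
#' @export
mid_fraction_columns <- function(mids) {
  mcols <- grep("^M[0-9]+$", names(mids), value = TRUE)
  if (!length(mcols)) stop("no M0..Mk fraction columns found", call. = FALSE)
  mcols[order(as.integer(sub("^M", "", mcols)))]
}

#' Extract the fraction matrix of an MID table
#' @param mids A `mid_table`.
#' @return Numeric matrix, one row per record, columns M0..Mk.
#' @export
mid_fractions <- function(mids) {
  as.matrix(as.data.frame(mids)[, mid_fraction_columns(mids), drop = FALSE])
}

#' Write an MID table
#' @param mids A `mid_table`.
#' @param path Output CSV path.
#' @param sep Field separator.
#' @export
write_mid_table <- function(mids, path, sep = ",") {
  df <- as.data.frame(mids)
  txt <- .text_cols(df)
  num <- vapply(df, is.numeric, logical(1))
  for (cn in names(df)[num]) df[[cn]] <- .fmt_num(df[[cn]])
  .write_csv(df, path, sep, quote_cols = txt)
  invisible(path)
}

#' Read an annotation table
#' @param path CSV with columns `feature_id`, `compound_name`, `formula`,
#'   `adduct`, `ppm_error`, `source` and optional `score`.
#' @param sep Field separator.
#' @return Annotation data frame.
#' @export
read_annotation_table <- function(path, sep = ",") {
  df <- .read_csv_raw(path, sep)
  .require_columns(df, c("feature_id", "compound_name", "source"),
                   "annotation table")
  if (!is.null(df$ppm_error))
    df$ppm_error <- .to_numeric(df$ppm_error, "ppm_error", "annotation table")
  if (!is.null(df$score))
    df$score <- .to_numeric(df$score, "score", "annotation table")
  bad <- setdiff(unique(df$source), c("ms1", "standard", "ms2"))
  if (length(bad))
    stop("annotation table: source must be ms1|standard|ms2, got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  df
}

#' Write an annotation table
#' @param annotations Annotation data frame.
#' @param path Output CSV path.
#' @param sep Field separator.
#' @export
write_annotation_table <- function(annotations, path, sep = ",") {
  df <- as.data.frame(annotations)
  txt <- .text_cols(df)
  num <- vapply(df, is.numeric, logical(1))
  for (cn in names(df)[num]) df[[cn]] <- .fmt_num(df[[cn]])
  .write_csv(df, path, sep, quote_cols = txt)
  invisible(path)
}

#' Cross-validate a feature table against a sample sheet
#'
#' Checks that every sample column of the feature table is declared in the
#' sample sheet.
#'
#' @param features A `feature_table`.
#' @param samples A `sample_sheet`.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_tables <- function(features, samples) {
  missing <- setdiff(sample_ids(features), samples$sample_id)
  if (length(missing))
    stop("feature table references samples absent from the sample sheet: ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}
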