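# MS1 accurate-mass annotation against a user-supplied compound table, and
# reference-standard matching by joint m/z + retention-time windows.
# Annotation is candidate generation: a feature may carry several candidates
# (many-to-many); there is no automatic best-hit collapse in annotate_ms1.

.empty_annotation <- function() {
  data.frame(feature_id = character(0), compound_name = character(0),
             formula = character(0), adduct = character(0),
             ppm_error = numeric(0), source = character(0),
             score = numeric(0), stringsAsFactors = FALSE)
}

#' Annotate features by accurate mass
#'
#' Matches each feature's m/z against every (compound, adduct) theoretical
#' m/z; every hit with |ppm error| at or below `ppm_tol` becomes one
#' annotation row with `source = "ms1"`. Hits for a feature are ordered by
#' absolute ppm error; features without hits are absent from the output.
#' Compound rows with unparseable formulas are skipped with a warning and
#' counted in the `skipped_formulas` attribute.
#'
#' @param features A `feature_table`.
#' @param compounds Data frame with columns `name`, `formula`.
#' @param adducts Adduct table as from [default_adducts()].
#' @param ppm_tol Two-sided mass tolerance in ppm (> 0), applied to m/z.
#' @return Annotation data frame (feature_id, compound_name, formula, adduct,
#'   ppm_error, source, score).
#' @export
annotate_ms1 <- function(features, compounds, adducts = default_adducts(),
                         ppm_tol = 5) {
  stopifnot(ppm_tol > 0)
  .require_columns(compounds, c("name", "formula"), "compound table")
  skipped <- character(0)
  rows <- list()
  for (i in seq_len(nrow(compounds))) {
    mass <- tryCatch(monoisotopic_mass(compounds$formula[i]),
                     error = function(e) NULL)
    if (is.null(mass)) {
      skipped <- c(skipped, compounds$name[i])
      next
    }
    for (j in seq_len(nrow(adducts))) {
      theo <- adduct_mz(mass, adducts[j, ])
      err <- ppm_error(features$mz, theo)
      hit <- which(abs(err) <= ppm_tol)
      if (length(hit))
        rows[[length(rows) + 1L]] <- data.frame(
          feature_id = features$feature_id[hit],
          compound_name = compounds$name[i],
          formula = compounds$formula[i],
          adduct = adducts$name[j],
          ppm_error = err[hit], source = "ms1", score = NA_real_,
          stringsAsFactors = FALSE)
    }
  }
  if (length(skipped))
    warning(length(skipped), " compound(s) with unparseable formula skipped: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  out <- if (length(rows)) do.call(rbind, rows) else .empty_annotation()
  out <- out[order(out$feature_id, abs(out$ppm_error), out$compound_name,
                   out$adduct), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped_formulas") <- skipped
  out
}

#' Match features to measured reference standards
#'
#' A feature matches a standard when its m/z is within `ppm_tol` of the
#' standard's measured m/z and its retention time within `rt_tol` seconds.
#' When several standards match one feature, the one with the smallest
#' combined normalized distance `|ppm|/ppm_tol + |drt|/rt_tol` wins; one
#' annotation row (`source = "standard"`) is emitted per matched feature.
#'
#' @param features A `feature_table`.
#' @param standards Data frame with columns `compound_name`, `formula`, `rt`
#'   (seconds), `mz` (Da).
#' @param ppm_tol Mass tolerance in ppm (> 0).
#' @param rt_tol Retention-time tolerance in seconds (> 0).
#' @return Annotation data frame.
#' @export
match_reference_standards <- function(features, standards, ppm_tol = 5,
                                      rt_tol = 10) {
  stopifnot(ppm_tol > 0, rt_tol > 0)
  .require_columns(standards, c("compound_name", "rt", "mz"),
                   "standards table")
  if (is.null(standards$formula)) standards$formula <- NA_character_
  rows <- list()
  for (i in seq_len(nrow(features))) {
    err <- ppm_error(features$mz[i], standards$mz)
    drt <- features$rt[i] - standards$rt
    ok <- which(abs(err) <= ppm_tol & abs(drt) <= rt_tol)
    if (!length(ok)) next
    dist <- abs(err[ok]) / ppm_tol + abs(drt[ok]) / rt_tol
    best <- ok[order(dist, standards$compound_name[ok])[1]]
    rows[[length(rows) + 1L]] <- data.frame(
      feature_id = features$feature_id[i],
      compound_name = standards$compound_name[best],
      formula = standards$formula[best], adduct = NA_character_,
      ppm_error = err[best], source = "standard", score = NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else .empty_annotation()
  rownames(out) <- NULL
  out
}
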