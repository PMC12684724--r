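# MS2 alignment to MS1 features and spectral-library matching. The
# similarity metric is the square-root-intensity cosine over greedily
# (closest-mz-first) one-to-one paired peaks, with unpaired peaks kept as
# mismatched vector entries — a standard untargeted-metabolomics choice.

#' Spectral similarity between two MS2 spectra
#'
#' Peaks of the two spectra are paired one-to-one within `mz_tol`, closest
#' mz difference first; the score is the cosine between the
#' square-root-scaled intensity vectors over paired plus unpaired peaks.
#' Symmetric; 1 for identical spectra, 0 for disjoint peak sets.
#'
#' @param a,b [ms2_spectrum()] objects (non-empty).
#' @param mz_tol Peak-matching tolerance in Da.
#' @return Score in \[0, 1\].
#' @export
spectral_similarity <- function(a, b, mz_tol = 0.01) {
  pa <- a$peaks; pb <- b$peaks
  if (!nrow(pa) || !nrow(pb))
    stop("spectral similarity undefined for an empty spectrum", call. = FALSE)
  dmz <- abs(outer(pa[, "mz"], pb[, "mz"], "-"))
  cand <- which(dmz <= mz_tol, arr.ind = TRUE)
  used_a <- logical(nrow(pa)); used_b <- logical(nrow(pb))
  pairs <- NULL
  if (nrow(cand)) {
    cand <- cand[order(dmz[cand]), , drop = FALSE]
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (!used_a[i] && !used_b[j]) {
        used_a[i] <- TRUE; used_b[j] <- TRUE
        pairs <- rbind(pairs, c(i, j))
      }
    }
  }
  va <- c(if (!is.null(pairs)) sqrt(pa[pairs[, 1], "intensity"]),
          sqrt(pa[!used_a, "intensity"]), rep(0, sum(!used_b)))
  vb <- c(if (!is.null(pairs)) sqrt(pb[pairs[, 2], "intensity"]),
          rep(0, sum(!used_a)), sqrt(pb[!used_b, "intensity"]))
  denom <- sqrt(sum(va^2)) * sqrt(sum(vb^2))
  if (denom == 0) return(0)
  min(1, max(0, sum(va * vb) / denom))
}

#' Align MS2 spectra to MS1 features
#'
#' Assigns each spectrum to the feature whose m/z lies within `ppm_tol` of
#' the precursor and whose retention time lies within `rt_tol`; when several
#' features qualify, the nearest precursor ppm wins. Spectra matching no
#' feature are reported unassigned.
#'
#' @param ms2 List of [ms2_spectrum()] objects.
#' @param features A `feature_table`.
#' @param ppm_tol Precursor tolerance in ppm (> 0).
#' @param rt_tol Retention-time tolerance in seconds (> 0).
#' @return List with `assigned` (data frame `spectrum`, `feature_id`,
#'   `ppm_error`, `delta_rt`) and `unassigned` (integer indices into `ms2`).
#' @export
align_ms2_to_features <- function(ms2, features, ppm_tol = 10, rt_tol = 15) {
  stopifnot(ppm_tol > 0, rt_tol > 0)
  assigned <- list(); unassigned <- integer(0)
  for (k in seq_along(ms2)) {
    s <- ms2[[k]]
    err <- ppm_error(s$precursor_mz, features$mz)
    drt <- if (is.na(s$rt)) rep(0, nrow(features)) else s$rt - features$rt
    ok <- which(abs(err) <= ppm_tol & abs(drt) <= rt_tol)
    if (!length(ok)) { unassigned <- c(unassigned, k); next }
    best <- ok[order(abs(err[ok]), features$feature_id[ok])[1]]
    assigned[[length(assigned) + 1L]] <- data.frame(
      spectrum = k, feature_id = features$feature_id[best],
      ppm_error = err[best], delta_rt = drt[best], stringsAsFactors = FALSE)
  }
  list(assigned = if (length(assigned)) do.call(rbind, assigned) else
         data.frame(spectrum = integer(0), feature_id = character(0),
                    ppm_error = numeric(0), delta_rt = numeric(0)),
       unassigned = unassigned)
}

#' Annotate features through MS2 library matching
#'
#' For every feature with assigned spectra, library entries whose precursor
#' lies within `ppm_tol` and whose [spectral_similarity()] against any
#' assigned spectrum reaches `min_score` become annotation rows with
#' `source = "ms2"`, ranked by score (best spectrum per entry).
#'
#' @param alignment Result of [align_ms2_to_features()].
#' @param ms2 The spectrum list passed to the alignment.
#' @param library List of named [ms2_spectrum()] objects.
#' @param mz_tol Peak-matching tolerance in Da for the similarity.
#' @param min_score Minimum similarity in \[0, 1\].
#' @param ppm_tol Precursor tolerance in ppm.
#' @return Annotation data frame.
#' @export
annotate_ms2 <- function(alignment, ms2, library, mz_tol = 0.01,
                         min_score = 0.7, ppm_tol = 10) {
  if (!is.numeric(min_score) || min_score < 0 || min_score > 1)
    stop("min_score must lie in [0, 1]", call. = FALSE)
  if (!length(library)) {
    warning("empty MS2 library; no annotations produced", call. = FALSE)
    return(.empty_annotation())
  }
  asg <- alignment$assigned
  rows <- list()
  for (fid in unique(asg$feature_id)) {
    spec_idx <- asg$spectrum[asg$feature_id == fid]
    for (li in seq_along(library)) {
      entry <- library[[li]]
      best <- -Inf; best_ppm <- NA_real_
      for (k in spec_idx) {
        s <- ms2[[k]]
        perr <- ppm_error(s$precursor_mz, entry$precursor_mz)
        if (abs(perr) > ppm_tol) next
        sc <- spectral_similarity(s, entry, mz_tol)
        if (sc > best) { best <- sc; best_ppm <- perr }
      }
      if (is.finite(best) && best >= min_score)
        rows[[length(rows) + 1L]] <- data.frame(
          feature_id = fid,
          compound_name = if (is.na(entry$name)) sprintf("library_%d", li)
                          else entry$name,
          formula = NA_character_, adduct = NA_character_,
          ppm_error = best_ppm, source = "ms2", score = best,
          stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else .empty_annotation()
  out <- out[order(out$feature_id, -out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}
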