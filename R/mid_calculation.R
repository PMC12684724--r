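# MID calculation with natural-abundance correction against the unlabeled
# condition. The unlabeled condition's measured MID is the correction kernel:
# the labeled MID is modeled as the convolution of the tracer-incorporation
# distribution with that kernel, and recovered by non-negative least squares
# against the shifted-kernel (lower-triangular) matrix. Truncated columns are
# deliberately NOT renormalized — lost tail mass surfaces in the residual
# instead of being hidden.

# zero-pad x to length L
.pad <- function(x, L) c(x, rep(0, L - length(x)))

#' Pool per-sample MID vectors
#'
#' Element-wise mean (renormalized to sum 1) and element-wise sample
#' standard deviation across replicate fraction vectors.
#'
#' @param per_sample_vectors List of equal-length fraction vectors, or a
#'   matrix with one row per sample.
#' @return List `mean` (sums to 1) and `sd` (zeros for a single vector).
#' @export
pooled_mid <- function(per_sample_vectors) {
  if (is.matrix(per_sample_vectors))
    per_sample_vectors <- asplit(per_sample_vectors, 1)
  stopifnot(length(per_sample_vectors) >= 1)
  lens <- lengths(per_sample_vectors)
  if (length(unique(lens)) != 1)
    stop("pooled_mid: vectors have differing lengths (",
         paste(unique(lens), collapse = ", "), ")", call. = FALSE)
  m <- do.call(rbind, per_sample_vectors)
  mu <- colMeans(m)
  mu <- mu / sum(mu)
  sdv <- if (nrow(m) == 1) rep(0, ncol(m)) else apply(m, 2, stats::sd)
  list(mean = unname(mu), sd = unname(sdv))
}

#' Correction matrix from an unlabeled MID
#'
#' Column j (0-based) is the unlabeled MID shifted down by j positions and
#' truncated at length L, without renormalization; column 0 is the unlabeled
#' MID itself.
#'
#' @param unlabeled_mid Fraction vector (non-negative, sums to 1).
#' @return L x L matrix.
#' @export
correction_matrix <- function(unlabeled_mid) {
  u <- unlabeled_mid
  stopifnot(all(u >= 0), abs(sum(u) - 1) < 1e-6)
  L <- length(u)
  C <- matrix(0, L, L)
  for (j in 0:(L - 1)) C[(j + 1):L, j + 1] <- u[1:(L - j)]
  C
}

#' Correct a labeled MID against the unlabeled condition
#'
#' Solves `min || C f - m ||_2` subject to `f >= 0`, where `C` is
#' [correction_matrix()] of the unlabeled MID and `m` the labeled MID
#' (vectors of unequal length are zero-padded to the longer). The corrected
#' MID is `f / sum(f)`; the residual is the reconstruction error before
#' normalization.
#'
#' @param labeled_mid,unlabeled_mid Fraction vectors summing to 1.
#' @return List `corrected` (on the simplex), `residual` (>= 0) and `raw`
#'   (the unnormalized solution).
#' @export
correct_mid <- function(labeled_mid, unlabeled_mid) {
  L <- max(length(labeled_mid), length(unlabeled_mid))
  m <- .pad(labeled_mid, L)
  u <- .pad(unlabeled_mid, L)
  stopifnot(abs(sum(m) - 1) < 1e-6, abs(sum(u) - 1) < 1e-6,
            all(m >= 0), all(u >= 0))
  if (L == 1)
    return(list(corrected = 1, residual = 0, raw = 1))
  C <- correction_matrix(u)
  fit <- pracma::lsqnonneg(C, m)
  f <- fit$x
  s <- sum(f)
  if (s <= 1e-12)
    stop("degenerate correction: non-negative solution has zero mass",
         call. = FALSE)
  list(corrected = f / s,
       residual = sqrt(sum((C %*% f - m)^2)),
       raw = f)
}

#' MID filter parameters
#'
#' The labeling filters applied to MID estimates: minimum enrichment in the
#' labeled samples, maximum labeling in the unlabeled samples (with an
#' optional formula-aware natural-tail allowance), minimum quantification,
#' maximum reconstruction residual and minimum replicate presence.
#'
#' @param min_labeled_enrichment Minimum `1 - corrected[M0]` in \[0, 1\].
#' @param max_unlabeled_labeling Maximum `1 - raw_unlabeled[M0]` in \[0, 1\].
#' @param min_quantification Minimum mean labeled total intensity.
#' @param min_replicate_fraction Minimum fraction of labeled replicates with
#'   any member signal, in (0, 1\].
#' @param max_residual Maximum correction residual.
#' @param natural_tail_allowance If `TRUE`, features annotated with a formula
#'   get the binomial natural expectation `1 - (1 - p)^nE` added to
#'   `max_unlabeled_labeling` (p = natural heavy fraction, nE = tracer-element
#'   count), so natural isotope tails of large molecules are not rejected.
#' @return A `mid_filter_params` list.
#' @export
mid_filter_params <- function(min_labeled_enrichment = 0.05,
                              max_unlabeled_labeling = 0.05,
                              min_quantification = 0,
                              min_replicate_fraction = 0.5,
                              max_residual = 0.05,
                              natural_tail_allowance = TRUE) {
  stopifnot(min_labeled_enrichment >= 0, min_labeled_enrichment <= 1,
            max_unlabeled_labeling >= 0, max_unlabeled_labeling <= 1,
            min_quantification >= 0,
            min_replicate_fraction > 0, min_replicate_fraction <= 1,
            max_residual >= 0)
  structure(list(min_labeled_enrichment = min_labeled_enrichment,
                 max_unlabeled_labeling = max_unlabeled_labeling,
                 min_quantification = min_quantification,
                 min_replicate_fraction = min_replicate_fraction,
                 max_residual = max_residual,
                 natural_tail_allowance = isTRUE(natural_tail_allowance)),
            class = "mid_filter_params")
}

#' Estimate corrected MIDs for detected groups
#'
#' Per group and condition: the raw labeled and unlabeled MIDs are the pooled
#' per-sample relative intensities ([pooled_mid()]; normalize first, then
#' average); the corrected MID comes from [correct_mid()]; its dispersion
#' from correcting each labeled replicate separately and taking the
#' element-wise sd; quantification is the mean (and sd) over labeled
#' replicates of the summed member intensities; enrichment is
#' `1 - corrected[M0]`.
#'
#' @param groups An `isotopologue_groups` data frame.
#' @param features A `feature_table`.
#' @param samples A `sample_sheet`.
#' @return A `mid_estimates` list, one element per (group, condition), each
#'   with fields `group_id`, `base_feature_id`, `condition`, `raw_labeled`,
#'   `raw_labeled_sd`, `raw_unlabeled`, `corrected`, `corrected_sd`,
#'   `residual`, `enrichment`, `quantification`, `quantification_sd`,
#'   `n_labeled_used`, `n_labeled_total`.
#' @export
estimate_mids <- function(groups, features, samples) {
  validate_tables(features, samples)
  missing <- setdiff(groups$feature_id, features$feature_id)
  if (length(missing))
    stop("groups reference feature(s) absent from the feature table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  keys <- unique(as.data.frame(groups)[, c("group_id", "condition")])
  out <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    gid <- keys$group_id[i]; cond <- keys$condition[i]
    members <- as.data.frame(groups)[groups$group_id == gid &
                                       groups$condition == cond, , drop = FALSE]
    members <- members[order(members$n), , drop = FALSE]
    # fill gap positions (member missing at some n below the highest observed)
    # with zero-intensity placeholders so the MID vector stays indexed by n
    full_n <- 0:max(members$n)
    if (length(full_n) > nrow(members)) {
      idx <- match(full_n, members$n)
      members <- members[idx, , drop = FALSE]
      members$n <- full_n
      rownames(members) <- NULL
    }
    lab_ids <- samples$sample_id[samples$condition == cond &
                                   samples$tracer_state == "labeled"]
    unl_ids <- resolve_unlabeled_samples(samples, cond)
    if (!length(lab_ids) || !length(unl_ids))
      stop("condition '", cond, "' lacks labeled or unlabeled samples",
           call. = FALSE)
    rel_l <- per_sample_relative_intensities(members, features, lab_ids)
    rel_u <- per_sample_relative_intensities(members, features, unl_ids)
    if (!nrow(rel_l) || !nrow(rel_u))
      stop("group '", gid, "': no sample with any member signal",
           call. = FALSE)
    pl <- pooled_mid(rel_l)
    pu <- pooled_mid(rel_u)
    L <- ncol(rel_l)
    if (L == 1) {
      corrected <- 1; corrected_sd <- 0; residual <- 0
    } else {
      cm <- correct_mid(pl$mean, pu$mean)
      corrected <- cm$corrected; residual <- cm$residual
      per_rep <- apply(rel_l, 1, function(v) {
        tryCatch(correct_mid(v, pu$mean)$corrected,
                 error = function(e) rep(NA_real_, L))
      })
      per_rep <- t(per_rep)
      corrected_sd <- if (nrow(per_rep) > 1)
        apply(per_rep, 2, stats::sd, na.rm = TRUE) else rep(0, L)
      corrected_sd[is.na(corrected_sd)] <- 0
    }
    # total member intensity per labeled sample (absent -> 0)
    ridx <- match(members$feature_id[!is.na(members$feature_id)],
                  features$feature_id)
    lm <- as.matrix(as.data.frame(features)[ridx, lab_ids, drop = FALSE])
    lm[is.na(lm)] <- 0
    totals <- colSums(lm)
    totals <- totals[totals > 0]
    out[[i]] <- list(
      group_id = gid, base_feature_id = members$base_feature_id[1],
      condition = cond,
      ns = members$n,
      raw_labeled = pl$mean, raw_labeled_sd = pl$sd,
      raw_unlabeled = pu$mean,
      corrected = as.numeric(corrected),
      corrected_sd = as.numeric(corrected_sd),
      residual = residual,
      enrichment = 1 - as.numeric(corrected)[1],
      quantification = if (length(totals)) mean(totals) else 0,
      quantification_sd = if (length(totals) > 1) stats::sd(totals) else 0,
      n_labeled_used = nrow(rel_l), n_labeled_total = length(lab_ids))
  }
  structure(out, class = "mid_estimates")
}

# binomial natural-labeling allowance 1 - (1-p)^nE for an annotated formula
.natural_allowance <- function(formula, tracer) {
  comp <- tryCatch(parse_formula(formula), error = function(e) NULL)
  if (is.null(comp) || !(tracer$element %in% names(comp))) return(0)
  nE <- comp[[tracer$element]]
  1 - (1 - tracer$natural_fraction)^nE
}

#' Filter MID estimates
#'
#' Applies the labeling filters in a fixed order — minimum labeled
#' enrichment, maximum unlabeled labeling, minimum quantification, maximum
#' residual, minimum replicate presence — and records the first failing
#' rule's name for every rejected estimate.
#'
#' @param estimates A `mid_estimates` list from [estimate_mids()].
#' @param params A [mid_filter_params()].
#' @param annotations Optional annotation data frame; when present and
#'   `natural_tail_allowance` is on, a base feature's annotated formula
#'   raises the unlabeled-labeling cap by the binomial natural expectation.
#' @param tracer A [tracer_def()] (for the allowance).
#' @return List `kept` (a `mid_estimates` list) and `rejected` (data frame
#'   `group_id`, `condition`, `reason`).
#' @export
filter_mids <- function(estimates, params = mid_filter_params(),
                        annotations = NULL, tracer = tracer_def("13C")) {
  kept <- list()
  rej <- list()
  for (e in estimates) {
    allowance <- 0
    if (params$natural_tail_allowance && !is.null(annotations)) {
      hit <- annotations[annotations$feature_id == e$base_feature_id &
                           !is.na(annotations$formula), , drop = FALSE]
      if (nrow(hit))
        allowance <- max(vapply(hit$formula, .natural_allowance, numeric(1),
                                tracer = tracer))
    }
    unlabeled_labeling <- 1 - e$raw_unlabeled[1]
    reason <- NULL
    if (e$enrichment < params$min_labeled_enrichment)
      reason <- "min_labeled_enrichment"
    else if (unlabeled_labeling > params$max_unlabeled_labeling + allowance)
      reason <- "max_unlabeled_labeling"
    else if (e$quantification < params$min_quantification)
      reason <- "min_quantification"
    else if (e$residual > params$max_residual)
      reason <- "max_residual"
    else if (e$n_labeled_used / e$n_labeled_total <
             params$min_replicate_fraction)
      reason <- "min_replicate_fraction"
    if (is.null(reason)) kept[[length(kept) + 1L]] <- e
    else rej[[length(rej) + 1L]] <- data.frame(
      group_id = e$group_id, condition = e$condition, reason = reason,
      stringsAsFactors = FALSE)
  }
  list(kept = structure(kept, class = "mid_estimates"),
       rejected = if (length(rej)) do.call(rbind, rej) else
         data.frame(group_id = character(0), condition = character(0),
                    reason = character(0), stringsAsFactors = FALSE))
}

#' Convert MID estimates to an MID table
#'
#' Builds the wide `mid_table` (M0..Mk and SD_0..SD_k columns, padded with
#' zeros to the longest vector) used by the contextualization module and the
#' CSV writer. Display names and the annotated flag come from the best
#' annotation of each group's base feature, when provided.
#'
#' @param estimates A `mid_estimates` list.
#' @param samples A `sample_sheet` (supplies the experiment label per
#'   condition).
#' @param annotations Optional annotation data frame.
#' @return A `mid_table`.
#' @export
as_mid_table <- function(estimates, samples, annotations = NULL) {
  if (!length(estimates)) stop("no MID estimates to convert", call. = FALSE)
  L <- max(vapply(estimates, function(e) length(e$corrected), integer(1)))
  cond_exp <- unique(as.data.frame(samples)[samples$tracer_state == "labeled",
                                            c("condition", "experiment")])
  rows <- lapply(estimates, function(e) {
    disp <- e$group_id; annotated <- FALSE
    if (!is.null(annotations)) {
      hit <- annotations[annotations$feature_id == e$base_feature_id, ,
                         drop = FALSE]
      if (nrow(hit)) {
        hit <- hit[order(abs(hit$ppm_error)), , drop = FALSE]
        disp <- hit$compound_name[1]
        annotated <- TRUE
      }
    }
    exp_lab <- cond_exp$experiment[match(e$condition, cond_exp$condition)]
    frac <- .pad(e$corrected, L)
    sds <- .pad(e$corrected_sd, L)
    df <- data.frame(node_id = e$group_id, display_name = disp,
                     condition = e$condition,
                     experiment = if (is.na(exp_lab)) "" else exp_lab,
                     stringsAsFactors = FALSE)
    for (k in seq_len(L)) df[[sprintf("M%d", k - 1L)]] <- frac[k]
    for (k in seq_len(L)) df[[sprintf("SD_%d", k - 1L)]] <- sds[k]
    df$enrichment <- e$enrichment
    df$quantification <- e$quantification
    df$quantification_sd <- e$quantification_sd
    df$residual <- e$residual
    df$annotated <- annotated
    df
  })
  mid_table(do.call(rbind, rows))
}
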