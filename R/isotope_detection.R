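# Non-targeted isotopologue-group detection. For each labeled condition,
# base features are scanned in descending mean unlabeled intensity; candidate
# isotopologues are features at base_mz + n * delta_mass / charge within a
# ppm window and an RT window; the labeled-vs-unlabeled shift in per-sample
# *relative* intensity at each position n >= 1 is tested with a Welch t-test.
# Features of retained groups are consumed so no feature joins two groups.

#' Detection parameters
#'
#' @param ppm_tol Mass window in ppm around each expected isotopologue m/z.
#' @param rt_window Retention-time window in seconds around the base feature.
#' @param n_max Highest isotopologue index searched.
#' @param charge Assumed charge of all features (single value per run).
#' @param alpha Significance level for the per-position Welch test.
#' @param noise_floor Minimum mean unlabeled intensity for a base feature.
#' @param min_replicates Minimum labeled and unlabeled replicates required.
#' @param require_enrichment_direction If `TRUE` (default) a position only
#'   counts when the labeled mean relative intensity exceeds the unlabeled
#'   mean there, i.e. the shift looks like enrichment, not depletion.
#' @param fdr If `TRUE`, Benjamini-Hochberg-adjust all retained p-values
#'   across the run and re-filter groups at `alpha` on the adjusted values.
#' @return A `detection_params` list.
#' @export
detection_params <- function(ppm_tol = 5, rt_window = 10, n_max = 10,
                             charge = 1, alpha = 0.05, noise_floor = 0,
                             min_replicates = 2,
                             require_enrichment_direction = TRUE,
                             fdr = FALSE) {
  stopifnot(ppm_tol > 0, rt_window > 0, n_max >= 1, charge >= 1,
            alpha > 0, alpha < 1, noise_floor >= 0, min_replicates >= 2)
  structure(list(ppm_tol = ppm_tol, rt_window = rt_window,
                 n_max = as.integer(n_max), charge = as.integer(charge),
                 alpha = alpha, noise_floor = noise_floor,
                 min_replicates = as.integer(min_replicates),
                 require_enrichment_direction =
                   isTRUE(require_enrichment_direction),
                 fdr = isTRUE(fdr)),
            class = "detection_params")
}

# Resolve the unlabeled counterpart of a labeled condition: unlabeled samples
# of the same condition if any, else of the same experiment(s), else all
# unlabeled samples.
resolve_unlabeled_samples <- function(samples, condition) {
  unl <- samples[samples$tracer_state == "unlabeled", , drop = FALSE]
  same_cond <- unl[unl$condition == condition, , drop = FALSE]
  if (nrow(same_cond)) return(same_cond$sample_id)
  exps <- unique(samples$experiment[samples$condition == condition])
  same_exp <- unl[unl$experiment %in% exps, , drop = FALSE]
  if (nrow(same_exp)) return(same_exp$sample_id)
  unl$sample_id
}

#' Candidate isotopologue members for a base feature
#'
#' For n = 1..`n_max`, features within `rt_window` of the base and within
#' `ppm_tol` of `base_mz + n * delta_mass / charge` are candidates; when
#' several features fall in one window the closest m/z is kept and the
#' ambiguity counted (attribute `n_ambiguous`). The n = 0 entry is the base
#' itself.
#'
#' @param features A `feature_table`.
#' @param base_feature_id Id of the base feature (must exist).
#' @param tracer A [tracer_def()].
#' @param params A [detection_params()].
#' @param exclude Feature ids not eligible as members (already consumed).
#' @return Data frame `n`, `feature_id`, `mz`, `rt`.
#' @export
candidate_members <- function(features, base_feature_id, tracer, params,
                              exclude = character(0)) {
  bi <- match(base_feature_id, features$feature_id)
  if (is.na(bi)) stop("base feature '", base_feature_id,
                      "' not in feature table", call. = FALSE)
  base_mz <- features$mz[bi]; base_rt <- features$rt[bi]
  eligible <- features$feature_id != base_feature_id &
    !(features$feature_id %in% exclude) &
    abs(features$rt - base_rt) <= params$rt_window
  out <- data.frame(n = 0L, feature_id = base_feature_id, mz = base_mz,
                    rt = base_rt, stringsAsFactors = FALSE)
  n_ambiguous <- 0L
  taken <- character(0)
  for (n in seq_len(params$n_max)) {
    target <- base_mz + n * tracer$delta_mass / params$charge
    tol <- params$ppm_tol * target * 1e-6
    hit <- which(eligible & abs(features$mz - target) <= tol &
                   !(features$feature_id %in% taken))
    if (!length(hit)) next
    if (length(hit) > 1) n_ambiguous <- n_ambiguous + 1L
    best <- hit[order(abs(features$mz[hit] - target))[1]]
    taken <- c(taken, features$feature_id[best])
    out <- rbind(out, data.frame(n = n, feature_id = features$feature_id[best],
                                 mz = features$mz[best], rt = features$rt[best],
                                 stringsAsFactors = FALSE))
  }
  attr(out, "n_ambiguous") <- n_ambiguous
  out
}

#' Per-sample relative intensities of a group
#'
#' For each sample, the member intensities (absent recorded as 0) are divided
#' by their sum, so every returned row sums to 1. Samples in which all
#' members are absent are dropped; an all-dropped result is an empty matrix
#' signaling insufficient data.
#'
#' @param members Member data frame as from [candidate_members()]. Rows with
#'   `NA` feature_id mark gap positions (a member missing at some n below the
#'   highest observed) and contribute zero intensity without truncating the
#'   group.
#' @param features A `feature_table`.
#' @param samples_subset Character vector of sample ids.
#' @return Numeric matrix, rows = retained samples, columns = member
#'   positions (named by `n`).
#' @export
per_sample_relative_intensities <- function(members, features, samples_subset) {
  stopifnot(nrow(members) >= 1, length(samples_subset) >= 1)
  present <- !is.na(members$feature_id)   # NA feature_id = gap position
  ridx <- match(members$feature_id[present], features$feature_id)
  if (any(is.na(ridx)))
    stop("group references feature(s) absent from the feature table: ",
         paste(members$feature_id[present][is.na(ridx)], collapse = ", "),
         call. = FALSE)
  m <- matrix(0, nrow(members), length(samples_subset))
  m[present, ] <- as.matrix(
    as.data.frame(features)[ridx, samples_subset, drop = FALSE])
  m[is.na(m)] <- 0
  m <- t(m)                                   # samples x positions
  colnames(m) <- as.character(members$n)
  rownames(m) <- samples_subset
  keep <- rowSums(m) > 0
  m <- m[keep, , drop = FALSE]
  m / rowSums(m)
}

#' Welch two-sample t-test
#'
#' The unequal-variance location test with Welch-Satterthwaite degrees of
#' freedom and a two-sided Student p-value. Degenerate zero-variance inputs
#' — which arise in noise-free simulations — are resolved explicitly: equal
#' means give t = 0, p = 1; unequal means give the p = 0 limit, flagged
#' `degenerate`.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return List `t`, `df`, `p`, `degenerate`.
#' @export
welch_t_test <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  dm <- mean(a) - mean(b)
  if (va == 0 && vb == 0) {
    if (dm == 0) return(list(t = 0, df = NA_real_, p = 1, degenerate = TRUE))
    return(list(t = sign(dm) * Inf, df = NA_real_, p = 0, degenerate = TRUE))
  }
  se2 <- va / na + vb / nb
  t <- dm / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p, degenerate = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
adjust_pvalues_bh <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Detect isotopologue groups for one labeled condition
#'
#' Iterates base features in descending mean unlabeled intensity; for each
#' unconsumed base above `noise_floor`, assembles [candidate_members()],
#' computes per-sample relative intensities separately for the labeled and
#' the (resolved) unlabeled sample set, and Welch-tests each position
#' n >= 1. A group is retained when at least one position has p <= `alpha`
#' (and, with `require_enrichment_direction`, a labeled mean above the
#' unlabeled mean at that position); its members are then consumed.
#'
#' @param features A `feature_table`.
#' @param samples A `sample_sheet`.
#' @param tracer A [tracer_def()].
#' @param params A [detection_params()].
#' @param condition Labeled condition to analyze.
#' @return An `isotopologue_groups` data frame in long format: `group_id`,
#'   `base_feature_id`, `condition`, `n`, `feature_id`, `mz`, `rt`,
#'   `p_value` (NA at n = 0 and untestable positions).
#' @export
detect_groups <- function(features, samples, tracer, params =
                            detection_params(), condition) {
  validate_tables(features, samples)
  lab_ids <- samples$sample_id[samples$condition == condition &
                                 samples$tracer_state == "labeled"]
  unl_ids <- resolve_unlabeled_samples(samples, condition)
  if (length(lab_ids) < params$min_replicates ||
      length(unl_ids) < params$min_replicates)
    stop(sprintf(paste0("condition '%s': need >= %d labeled and unlabeled ",
                        "replicates (found %d labeled, %d unlabeled)"),
                 condition, params$min_replicates, length(lab_ids),
                 length(unl_ids)), call. = FALSE)
  unl_mat <- as.matrix(as.data.frame(features)[, unl_ids, drop = FALSE])
  unl_mean <- rowMeans(replace(unl_mat, is.na(unl_mat), 0))
  order_idx <- order(-unl_mean, features$feature_id)
  consumed <- character(0)
  groups <- list()
  gcount <- 0L
  for (bi in order_idx) {
    fid <- features$feature_id[bi]
    if (fid %in% consumed) next
    if (unl_mean[bi] <= params$noise_floor) next
    members <- candidate_members(features, fid, tracer, params,
                                 exclude = consumed)
    if (nrow(members) < 2) next
    rel_l <- per_sample_relative_intensities(members, features, lab_ids)
    rel_u <- per_sample_relative_intensities(members, features, unl_ids)
    if (nrow(rel_l) < params$min_replicates ||
        nrow(rel_u) < params$min_replicates) next
    pos <- which(members$n >= 1)
    pvals <- rep(NA_real_, nrow(members))
    direction <- rep(FALSE, nrow(members))
    for (k in pos) {
      wt <- welch_t_test(rel_l[, k], rel_u[, k])
      pvals[k] <- wt$p
      direction[k] <- mean(rel_l[, k]) > mean(rel_u[, k])
    }
    hit <- !is.na(pvals) & pvals <= params$alpha &
      (!params$require_enrichment_direction | direction)
    if (!any(hit)) next
    gcount <- gcount + 1L
    gid <- sprintf("%s_G%03d", condition, gcount)
    groups[[gcount]] <- data.frame(
      group_id = gid, base_feature_id = fid, condition = condition,
      n = members$n, feature_id = members$feature_id, mz = members$mz,
      rt = members$rt, p_value = pvals, stringsAsFactors = FALSE)
    consumed <- c(consumed, members$feature_id)
  }
  out <- if (length(groups)) do.call(rbind, groups) else
    data.frame(group_id = character(0), base_feature_id = character(0),
               condition = character(0), n = integer(0),
               feature_id = character(0), mz = numeric(0), rt = numeric(0),
               p_value = numeric(0), stringsAsFactors = FALSE)
  if (params$fdr && nrow(out)) {
    testable <- !is.na(out$p_value)
    out$p_adjusted <- NA_real_
    out$p_adjusted[testable] <- adjust_pvalues_bh(out$p_value[testable])
    keep_gid <- unique(out$group_id[testable &
                                      out$p_adjusted <= params$alpha])
    out <- out[out$group_id %in% keep_gid, , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("isotopologue_groups", "data.frame")
  out
}

#' Detect isotopologue groups for every labeled condition
#'
#' Runs [detect_groups()] independently per labeled condition against its
#' matched unlabeled set and row-binds the results.
#'
#' @inheritParams detect_groups
#' @return Combined `isotopologue_groups` data frame.
#' @export
detect_all_groups <- function(features, samples, tracer,
                              params = detection_params()) {
  conds <- unique(samples$condition[samples$tracer_state == "labeled"])
  if (!length(conds))
    stop("sample sheet has no labeled condition", call. = FALSE)
  out <- do.call(rbind, lapply(conds, function(cc)
    detect_groups(features, samples, tracer, params, cc)))
  rownames(out) <- NULL
  class(out) <- c("isotopologue_groups", "data.frame")
  out
}

#' Write / read detected groups as CSV
#' @param groups An `isotopologue_groups` data frame.
#' @param path CSV path.
#' @param sep Field separator.
#' @export
write_groups_csv <- function(groups, path, sep = ",") {
  df <- as.data.frame(groups)
  for (cn in c("mz", "rt", "p_value", "p_adjusted"))
    if (!is.null(df[[cn]])) df[[cn]] <- .fmt_num(df[[cn]])
  .write_csv(df, path, sep,
             quote_cols = c("group_id", "base_feature_id", "condition",
                            "feature_id"))
  invisible(path)
}

#' @rdname write_groups_csv
#' @return `read_groups_csv`: an `isotopologue_groups` data frame.
#' @export
read_groups_csv <- function(path, sep = ",") {
  df <- .read_csv_raw(path, sep)
  .require_columns(df, c("group_id", "base_feature_id", "condition", "n",
                         "feature_id", "mz", "rt"), "groups table")
  df$n <- as.integer(.to_numeric(df$n, "n", "groups table"))
  for (cn in c("mz", "rt", "p_value", "p_adjusted"))
    if (!is.null(df[[cn]])) df[[cn]] <- .to_numeric(df[[cn]], cn, "groups table")
  class(df) <- c("isotopologue_groups", "data.frame")
  df
}
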