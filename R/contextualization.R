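# MID-similarity contextualization: metabolites sharing a pathway acquire
# related labeling patterns, so similarity of corrected MIDs across
# experiments and conditions links unknown features to annotated ones. The
# network is built over all node pairs, thresholded, filterable by degree,
# and exportable as Cytoscape JSON; annotated nodes can be mapped onto a
# reference pathway and each pathway metabolite's nearest unknown neighbors
# ranked.

#' Similarity between two MID vectors
#'
#' Vectors of unequal length are zero-padded. `"cosine"` is the standard
#' cosine; `"euclidean"` is `1 - ||a - b|| / sqrt(2)`, the Euclidean distance
#' normalized by the simplex diameter. Both are symmetric, 1 for identical
#' vectors, and bounded in \[0, 1\] for MIDs.
#'
#' @param a,b Fraction vectors.
#' @param metric `"cosine"` or `"euclidean"`.
#' @return Similarity in \[0, 1\].
#' @export
mid_similarity <- function(a, b, metric = c("cosine", "euclidean")) {
  if (is.character(metric) && length(metric) == 1 &&
      !metric %in% c("cosine", "euclidean"))
    stop("unknown similarity metric '", metric, "'", call. = FALSE)
  metric <- match.arg(metric)
  L <- max(length(a), length(b))
  a <- .pad(a, L); b <- .pad(b, L)
  if (metric == "cosine") {
    denom <- sqrt(sum(a^2)) * sqrt(sum(b^2))
    if (denom == 0) return(0)
    s <- sum(a * b) / denom
  } else {
    s <- 1 - sqrt(sum((a - b)^2)) / sqrt(2)
  }
  min(1, max(0, s))
}

#' Combined similarity of two nodes across shared conditions
#'
#' Computes [mid_similarity()] per (experiment, condition) record shared by
#' both nodes and combines with the mean (default) or the minimum.
#' Conditions present in only one node are skipped and counted.
#'
#' @param mids_a,mids_b `mid_table` subsets holding the records of the two
#'   nodes.
#' @param metric Similarity metric.
#' @param combine `"mean"` or `"min"`.
#' @return List `similarity` (`NA` when no shared condition), `n_shared`,
#'   `n_skipped`.
#' @export
combined_similarity <- function(mids_a, mids_b,
                                metric = c("cosine", "euclidean"),
                                combine = c("mean", "min")) {
  combine <- match.arg(combine)
  key_a <- paste(mids_a$experiment, mids_a$condition, sep = "\r")
  key_b <- paste(mids_b$experiment, mids_b$condition, sep = "\r")
  shared <- intersect(key_a, key_b)
  n_skipped <- length(setdiff(union(key_a, key_b), shared))
  if (!length(shared))
    return(list(similarity = NA_real_, n_shared = 0L, n_skipped = n_skipped))
  fa <- mid_fractions(mids_a); fb <- mid_fractions(mids_b)
  sims <- vapply(shared, function(k) {
    mid_similarity(fa[match(k, key_a), ], fb[match(k, key_b), ], metric)
  }, numeric(1))
  list(similarity = if (combine == "mean") mean(sims) else min(sims),
       n_shared = length(shared), n_skipped = n_skipped)
}

#' Per-node summary statistics across experiments and conditions
#'
#' Mean and standard deviation of enrichment and quantification over each
#' node's (experiment, condition) records, with the record count — the
#' between-experiment variability of labeling amount and quantity.
#'
#' @param mids A `mid_table`.
#' @return Data frame, one row per node.
#' @export
condition_stats <- function(mids) {
  df <- as.data.frame(mids)
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  out <- do.call(rbind, lapply(split(df, df$node_id), function(g) {
    data.frame(node_id = g$node_id[1],
               display_name = g$display_name[1],
               annotated = any(g$annotated),
               n_records = nrow(g),
               mean_enrichment = mean(g$enrichment),
               sd_enrichment = sd0(g$enrichment),
               mean_quantification = mean(g$quantification),
               sd_quantification = sd0(g$quantification),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$node_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build an MID-similarity network
#'
#' Scores every unordered node pair with [combined_similarity()] and keeps
#' edges at or above `threshold`; isolated nodes are retained. Edges are
#' stored canonically with `node_a < node_b`, so the result is independent of
#' input row order.
#'
#' @param mids A `mid_table` with >= 2 distinct nodes.
#' @param threshold Similarity threshold in \[0, 1\].
#' @param metric Similarity metric.
#' @param combine Cross-condition combination rule.
#' @return A `context_network`: list with `nodes` (from
#'   [condition_stats()]), `edges`, `node_mids` (per-node mean fraction
#'   vector, renormalized), `mids` (the input table) and `provenance`.
#' @export
build_network <- function(mids, threshold = 0.9,
                          metric = c("cosine", "euclidean"),
                          combine = c("mean", "min")) {
  if (is.character(metric) && length(metric) == 1 &&
      !metric %in% c("cosine", "euclidean"))
    stop("unknown similarity metric '", metric, "'", call. = FALSE)
  metric <- match.arg(metric)
  combine <- match.arg(combine)
  stopifnot(threshold >= 0, threshold <= 1)
  df <- as.data.frame(mids)
  ids <- sort(unique(df$node_id))
  if (length(ids) < 2)
    stop("network needs at least 2 distinct nodes", call. = FALSE)
  nodes <- condition_stats(mids)
  frac <- mid_fractions(mids)
  node_mids <- stats::setNames(lapply(ids, function(id) {
    v <- colMeans(frac[df$node_id == id, , drop = FALSE])
    unname(v / sum(v))
  }), ids)
  by_node <- split(seq_len(nrow(df)), df$node_id)
  edges <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      cs <- combined_similarity(mids[by_node[[ids[i]]], , drop = FALSE],
                                mids[by_node[[ids[j]]], , drop = FALSE],
                                metric, combine)
      if (is.na(cs$similarity) || cs$similarity < threshold) next
      edges[[length(edges) + 1L]] <- data.frame(
        node_a = ids[i], node_b = ids[j], similarity = cs$similarity,
        metric = metric, condition_scope = "combined",
        n_shared = cs$n_shared, stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(node_a = character(0), node_b = character(0),
               similarity = numeric(0), metric = character(0),
               condition_scope = character(0), n_shared = integer(0),
               stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, node_mids = node_mids,
                 mids = mids,
                 provenance = list(threshold = threshold, metric = metric,
                                   combine = combine)),
            class = "context_network")
}

#' Filter a contextualization network
#'
#' Drops edges below `min_similarity`, then — in a single deterministic pass,
#' degrees computed once after the edge drop — drops nodes whose degree falls
#' outside `[min_degree, max_degree]` together with their edges.
#'
#' @param network A `context_network`.
#' @param min_similarity Minimum edge similarity.
#' @param min_degree,max_degree Node degree bounds.
#' @return Filtered `context_network`.
#' @export
filter_network <- function(network, min_similarity = 0, min_degree = 0,
                           max_degree = Inf) {
  stopifnot(inherits(network, "context_network"))
  edges <- network$edges[network$edges$similarity >= min_similarity, ,
                         drop = FALSE]
  deg <- table(factor(c(edges$node_a, edges$node_b),
                      levels = network$nodes$node_id))
  keep <- network$nodes$node_id[deg >= min_degree & deg <= max_degree]
  nodes <- network$nodes[network$nodes$node_id %in% keep, , drop = FALSE]
  edges <- edges[edges$node_a %in% keep & edges$node_b %in% keep, ,
                 drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  out <- network
  out$nodes <- nodes
  out$edges <- edges
  out$node_mids <- network$node_mids[keep]
  out$provenance <- c(network$provenance,
                      list(filter = list(min_similarity = min_similarity,
                                         min_degree = min_degree,
                                         max_degree = max_degree)))
  out
}

#' Map context nodes onto a reference pathway
#'
#' Matches pathway nodes to context nodes by exact equality of the pathway
#' matching key (the `id_attribute` chosen at load) with the context
#' `node_id`, optionally case-insensitively. Matched pathway nodes carry the
#' node's enrichment, quantification and mean MID; unmatched ones are
#' flagged. Duplicate non-empty matching keys in the pathway are an error.
#'
#' @param network A `context_network`.
#' @param pathway A `pathway_graph` from [read_pathway_cyjs()].
#' @param case_insensitive Compare identifiers case-insensitively.
#' @return A `pathway_overlay`: list `pathway`, `matches` (data frame
#'   `pathway_id`, `match_key`, `node_id`, `mean_enrichment`,
#'   `mean_quantification`), `unmatched` (pathway ids), `node_mids`.
#' @export
map_to_pathway <- function(network, pathway, case_insensitive = TRUE) {
  stopifnot(inherits(network, "context_network"),
            inherits(pathway, "pathway_graph"))
  keys <- pathway$nodes$match_key
  nonempty <- keys[nzchar(keys)]
  dup <- unique(nonempty[duplicated(nonempty)])
  if (length(dup))
    stop("pathway has duplicated matching identifier(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  ctx_ids <- network$nodes$node_id
  norm <- function(x) if (case_insensitive) tolower(x) else x
  idx <- match(norm(keys), norm(ctx_ids))
  idx[!nzchar(keys)] <- NA
  matched <- which(!is.na(idx))
  matches <- data.frame(
    pathway_id = pathway$nodes$id[matched],
    match_key = keys[matched],
    node_id = ctx_ids[idx[matched]],
    mean_enrichment = network$nodes$mean_enrichment[idx[matched]],
    mean_quantification = network$nodes$mean_quantification[idx[matched]],
    stringsAsFactors = FALSE)
  structure(list(pathway = pathway, matches = matches,
                 unmatched = pathway$nodes$id[is.na(idx)],
                 node_mids = network$node_mids[matches$node_id]),
            class = "pathway_overlay")
}

#' Nearest unknown neighbors of a node
#'
#' Among a node's network neighbors with `annotated = FALSE`, the top `k` by
#' similarity, ties broken lexicographically by node id.
#'
#' @param network A `context_network`.
#' @param node_id Node to query (must exist).
#' @param k Number of neighbors to return.
#' @return Data frame `node_id`, `similarity`, ranked.
#' @export
nearest_unknown_neighbors <- function(network, node_id, k = 5) {
  stopifnot(inherits(network, "context_network"))
  if (!node_id %in% network$nodes$node_id)
    stop("unknown node '", node_id, "'", call. = FALSE)
  e <- network$edges
  nb <- rbind(
    data.frame(node_id = e$node_b[e$node_a == node_id],
               similarity = e$similarity[e$node_a == node_id],
               stringsAsFactors = FALSE),
    data.frame(node_id = e$node_a[e$node_b == node_id],
               similarity = e$similarity[e$node_b == node_id],
               stringsAsFactors = FALSE))
  ann <- network$nodes$annotated[match(nb$node_id, network$nodes$node_id)]
  nb <- nb[!ann, , drop = FALSE]
  nb <- nb[order(-nb$similarity, nb$node_id), , drop = FALSE]
  out <- utils::head(nb, k)
  rownames(out) <- NULL
  out
}
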