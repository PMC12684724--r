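# Cytoscape JSON (.cyjs) interchange, per the "elements" schema:
# elements$nodes[[i]]$data$id, elements$edges[[i]]$data${source,target}.
# Numbers are serialized with full precision (jsonlite digits = NA) so a
# write -> read round trip preserves MID vectors to the last digit.

#' Read a reference pathway in Cytoscape JSON format
#'
#' @param path `.cyjs` file.
#' @param id_attribute Optional name of the node `data` attribute holding the
#'   identifier used for matching (e.g. `"kegg"`). Nodes lacking the
#'   attribute load with an empty matching key and a warning.
#' @return A `pathway_graph`: list with `nodes` (data frame `id`, `label`,
#'   `match_key`) and `edges` (data frame `source`, `target`).
#' @export
read_pathway_cyjs <- function(path, id_attribute = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  els <- if (!is.null(j$elements)) j$elements else j
  nodes <- els$nodes
  edges <- els$edges
  if (is.null(nodes)) stop("Cytoscape JSON: no elements$nodes", call. = FALSE)
  get_chr <- function(x) if (is.null(x)) NA_character_ else as.character(x)
  nd <- lapply(nodes, function(no) {
    d <- no$data
    if (is.null(d$id)) stop("Cytoscape JSON: node without data.id",
                            call. = FALSE)
    key <- ""
    if (!is.null(id_attribute) && !is.null(d[[id_attribute]]))
      key <- as.character(d[[id_attribute]])
    list(id = as.character(d$id),
         label = if (!is.null(d$name)) get_chr(d$name) else as.character(d$id),
         match_key = key, data = d)
  })
  ids <- vapply(nd, `[[`, character(1), "id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("Cytoscape JSON: duplicated node id: ", paste(dup, collapse = ", "),
         call. = FALSE)
  if (!is.null(id_attribute)) {
    nokey <- sum(!nzchar(vapply(nd, `[[`, character(1), "match_key")))
    if (nokey > 0)
      warning(nokey, " node(s) lack attribute '", id_attribute,
              "'; loaded with empty matching key", call. = FALSE)
  }
  ed <- data.frame(source = character(0), target = character(0),
                   stringsAsFactors = FALSE)
  if (length(edges)) {
    ed <- data.frame(
      source = vapply(edges, function(e) as.character(e$data$source),
                      character(1)),
      target = vapply(edges, function(e) as.character(e$data$target),
                      character(1)),
      stringsAsFactors = FALSE)
    bad <- setdiff(unique(c(ed$source, ed$target)), ids)
    if (length(bad))
      stop("Cytoscape JSON: edge references unknown node(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(
    nodes = data.frame(id = ids,
                       label = vapply(nd, `[[`, character(1), "label"),
                       match_key = vapply(nd, `[[`, character(1), "match_key"),
                       stringsAsFactors = FALSE),
    edges = ed,
    node_data = lapply(nd, `[[`, "data")
  ), class = "pathway_graph")
}

#' Write a contextualization network as Cytoscape JSON
#'
#' Node `data` carries id, name, the annotated flag, mean enrichment and
#' quantification, and the per-node mean MID vector; edge `data` carries
#' source, target and the similarity score. Reading the file back with
#' [read_pathway_cyjs()] reproduces the node and edge sets exactly.
#'
#' @param network A `context_network` from [build_network()].
#' @param path Output `.cyjs` path.
#' @return The path, invisibly.
#' @export
write_network_cyjs <- function(network, path) {
  stopifnot(inherits(network, "context_network"))
  nodes <- lapply(seq_len(nrow(network$nodes)), function(i) {
    r <- network$nodes[i, ]
    mid <- network$node_mids[[r$node_id]]
    list(data = list(
      id = r$node_id, name = r$display_name, annotated = r$annotated,
      enrichment = r$mean_enrichment, quantification = r$mean_quantification,
      mid = as.list(if (is.null(mid)) numeric(0) else mid)))
  })
  edges <- lapply(seq_len(nrow(network$edges)), function(i) {
    r <- network$edges[i, ]
    list(data = list(id = paste0(r$node_a, "~", r$node_b),
                     source = r$node_a, target = r$node_b,
                     similarity = r$similarity))
  })
  out <- list(format_version = "1.0",
              data = list(name = "midcontext network",
                          provenance = network$provenance),
              elements = list(nodes = nodes, edges = edges))
  json <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, null = "null",
                           pretty = TRUE)
  ok <- tryCatch({ writeLines(json, path, useBytes = TRUE); TRUE },
                 error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write '", path, "': ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Read back a network written by [write_network_cyjs()]
#'
#' Reconstructs node attributes (annotated flag, enrichment, quantification,
#' MID vector) and weighted edges from a `.cyjs` file.
#'
#' @param path `.cyjs` file.
#' @return A `context_network`.
#' @export
read_network_cyjs <- function(path) {
  g <- read_pathway_cyjs(path)
  num_or_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  nodes <- do.call(rbind, lapply(g$node_data, function(d) {
    data.frame(node_id = as.character(d$id),
               display_name = if (!is.null(d$name)) as.character(d$name)
                              else as.character(d$id),
               annotated = isTRUE(d$annotated),
               mean_enrichment = num_or_na(d$enrichment),
               mean_quantification = num_or_na(d$quantification),
               stringsAsFactors = FALSE)
  }))
  node_mids <- stats::setNames(
    lapply(g$node_data, function(d) as.numeric(unlist(d$mid))),
    nodes$node_id)
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  eds <- j$elements$edges
  edges <- data.frame(node_a = character(0), node_b = character(0),
                      similarity = numeric(0), stringsAsFactors = FALSE)
  if (length(eds))
    edges <- data.frame(
      node_a = vapply(eds, function(e) as.character(e$data$source), character(1)),
      node_b = vapply(eds, function(e) as.character(e$data$target), character(1)),
      similarity = vapply(eds, function(e) as.numeric(e$data$similarity),
                          numeric(1)),
      stringsAsFactors = FALSE)
  prov <- j$data$provenance
  structure(list(nodes = nodes, edges = edges, node_mids = node_mids,
                 mids = NULL, provenance = prov),
            class = "context_network")
}
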