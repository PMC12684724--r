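test_that("MID similarity metrics hit their boundary cases", {
  expect_equal(mid_similarity(c(0.5, 0.5), c(0.5, 0.5), "cosine"), 1)
  expect_equal(mid_similarity(c(0.5, 0.5), c(0.5, 0.5), "euclidean"), 1)
  expect_equal(mid_similarity(c(1, 0), c(0, 1), "cosine"), 0)
  expect_equal(mid_similarity(c(1, 0), c(0, 1), "euclidean"), 0)
  # zero-padding aligns unequal lengths
  expect_equal(mid_similarity(c(1), c(1, 0), "cosine"), 1)
  expect_error(mid_similarity(c(1, 0), c(0, 1), "tanimoto"), "metric")
})

test_that("combined similarity averages or minimizes over shared conditions", {
  mt <- make_mid_table(list(X = c(0.8, 0.2), Y = c(0.8, 0.2)),
                       conditions = c("A", "B"))
  a <- mt[mt$node_id == "X", ]; b <- mt[mt$node_id == "Y", ]
  cs <- combined_similarity(a, b)
  expect_equal(cs$similarity, 1)
  expect_equal(cs$n_shared, 2)

  # differing vectors in one condition: mean vs min diverge
  mt2 <- rbind(make_mid_table(list(X = c(0.8, 0.2)), conditions = "A"),
               make_mid_table(list(X = c(0.2, 0.8)), conditions = "B"),
               make_mid_table(list(Y = c(0.8, 0.2)), conditions = c("A", "B")))
  mt2 <- mid_table(mt2)
  a2 <- mt2[mt2$node_id == "X", ]; b2 <- mt2[mt2$node_id == "Y", ]
  s_a <- mid_similarity(c(0.8, 0.2), c(0.8, 0.2))
  s_b <- mid_similarity(c(0.2, 0.8), c(0.8, 0.2))
  expect_equal(combined_similarity(a2, b2, combine = "mean")$similarity,
               mean(c(s_a, s_b)), tolerance = 1e-12)
  expect_equal(combined_similarity(a2, b2, combine = "min")$similarity,
               min(s_a, s_b), tolerance = 1e-12)

  # disjoint condition sets -> no comparable pair
  mt3 <- rbind(make_mid_table(list(X = c(0.8, 0.2)), conditions = "A"),
               make_mid_table(list(Y = c(0.8, 0.2)), conditions = "B"))
  mt3 <- mid_table(mt3)
  cs3 <- combined_similarity(mt3[mt3$node_id == "X", ],
                             mt3[mt3$node_id == "Y", ])
  expect_true(is.na(cs3$similarity))
})

test_that("network construction thresholds edges and keeps isolated nodes", {
  mt <- make_mid_table(list(A = c(0.9, 0.1, 0), B = c(0.85, 0.15, 0),
                            C = c(0.1, 0.1, 0.8)))
  net <- build_network(mt, threshold = 0.5)
  sims <- c(AB = mid_similarity(c(0.9, 0.1, 0), c(0.85, 0.15, 0)),
            AC = mid_similarity(c(0.9, 0.1, 0), c(0.1, 0.1, 0.8)),
            BC = mid_similarity(c(0.85, 0.15, 0), c(0.1, 0.1, 0.8)))
  expect_equal(nrow(net$edges), sum(sims >= 0.5))
  expect_equal(nrow(net$nodes), 3)         # isolated nodes retained

  full <- build_network(mt, threshold = 0)
  expect_equal(nrow(full$edges), 3)        # n(n-1)/2
  none <- build_network(mt, threshold = 1)
  expect_equal(nrow(none$edges), 0)
  expect_error(build_network(mt, metric = "manhattan"), "metric")
  expect_error(build_network(mt[mt$node_id == "A", ]), "2 distinct")
})

test_that("10-node networks match the brute-force oracle for all settings", {
  set.seed(41)
  fracs <- setNames(lapply(1:10, function(i) r_simplex(4)),
                    sprintf("N%02d", 1:10))
  mt <- make_mid_table(fracs, conditions = c("A", "B"))
  cos_o <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  euc_o <- function(a, b) 1 - sqrt(sum((a - b)^2)) / sqrt(2)
  for (metric in c("cosine", "euclidean")) {
    for (combine in c("mean", "min")) {
      net <- build_network(mt, threshold = 0, metric = metric,
                           combine = combine)
      ids <- sort(names(fracs))
      for (i in seq_along(ids)) for (j in seq_along(ids)) {
        if (j <= i) next
        # identical records in A and B -> per-condition sims equal
        o <- if (metric == "cosine") cos_o(fracs[[ids[i]]], fracs[[ids[j]]])
             else euc_o(fracs[[ids[i]]], fracs[[ids[j]]])
        e <- net$edges[net$edges$node_a == ids[i] &
                         net$edges$node_b == ids[j], ]
        expect_equal(e$similarity, o, tolerance = 1e-12)
      }
    }
  }
})

test_that("network output is independent of node input order", {
  set.seed(43)
  fracs <- setNames(lapply(1:6, function(i) r_simplex(3)),
                    sprintf("N%d", 1:6))
  mt <- make_mid_table(fracs)
  net1 <- build_network(mt, threshold = 0.3)
  mt_perm <- mid_table(as.data.frame(mt)[sample(nrow(mt)), ])
  net2 <- build_network(mt_perm, threshold = 0.3)
  expect_equal(net1$edges[, c("node_a", "node_b", "similarity")],
               net2$edges[, c("node_a", "node_b", "similarity")],
               ignore_attr = TRUE)
  expect_true(all(net1$edges$node_a < net1$edges$node_b))
})

test_that("raising the threshold only removes edges", {
  set.seed(47)
  fracs <- setNames(lapply(1:8, function(i) r_simplex(3)),
                    sprintf("N%d", 1:8))
  mt <- make_mid_table(fracs)
  prev <- NULL
  for (thr in c(0, 0.25, 0.5, 0.75, 0.95)) {
    net <- build_network(mt, threshold = thr)
    key <- paste(net$edges$node_a, net$edges$node_b)
    if (!is.null(prev)) expect_true(all(key %in% prev))
    prev <- key
  }
})

test_that("degree filtering removes hubs in a single deterministic pass", {
  # star: center H connected to 5 satellites
  fracs <- c(list(H = c(0.5, 0.5)),
             setNames(replicate(5, c(0.5, 0.5), simplify = FALSE),
                      sprintf("S%d", 1:5)))
  mt <- make_mid_table(fracs)
  net <- build_network(mt, threshold = 0)
  star <- net
  star$edges <- net$edges[net$edges$node_a == "H" | net$edges$node_b == "H", ]
  filt <- filter_network(star, max_degree = 4)
  expect_false("H" %in% filt$nodes$node_id)
  expect_equal(nrow(filt$edges), 0)

  # identity filter changes nothing
  same <- filter_network(net, min_similarity = 0, min_degree = 0,
                         max_degree = Inf)
  expect_equal(same$edges, net$edges)

  # all edges below cutoff: nodes with min_degree 0 survive edgeless
  empty <- filter_network(net, min_similarity = 1.1)
  expect_equal(nrow(empty$edges), 0)
  expect_equal(nrow(empty$nodes), nrow(net$nodes))
})

test_that("pathway mapping matches identifiers and flags the rest", {
  mt <- make_mid_table(list(C00031 = c(0.7, 0.3), U1 = c(0.7, 0.3),
                            U2 = c(0.2, 0.8)), annotated = "C00031")
  net <- build_network(mt, threshold = 0)
  p <- withr::local_tempfile(fileext = ".cyjs")
  pw <- list(elements = list(
    nodes = list(list(data = list(id = "n1", name = "glucose",
                                  kegg = "C00031")),
                 list(data = list(id = "n2", name = "mystery",
                                  kegg = "C99999"))),
    edges = list(list(data = list(source = "n1", target = "n2")))))
  jsonlite::write_json(pw, p, auto_unbox = TRUE)
  g <- read_pathway_cyjs(p, id_attribute = "kegg")
  ov <- map_to_pathway(net, g)
  expect_equal(ov$matches$pathway_id, "n1")
  expect_equal(ov$matches$node_id, "C00031")
  expect_equal(ov$unmatched, "n2")

  # duplicated matching identifiers are an error
  pw$elements$nodes[[2]]$data$kegg <- "C00031"
  jsonlite::write_json(pw, p, auto_unbox = TRUE)
  g2 <- read_pathway_cyjs(p, id_attribute = "kegg")
  expect_error(map_to_pathway(net, g2), "C00031")
})

test_that("nearest unknown neighbors rank by similarity with stable ties", {
  mt <- make_mid_table(list(K = c(0.5, 0.5, 0), U_a = c(0.5, 0.49, 0.01),
                            U_b = c(0.45, 0.45, 0.10),
                            U_c = c(0.1, 0.1, 0.8), K2 = c(0.5, 0.5, 0)),
                       annotated = c("K", "K2"))
  net <- build_network(mt, threshold = 0)
  nn <- nearest_unknown_neighbors(net, "K", k = 2)
  expect_equal(nrow(nn), 2)
  expect_false(any(c("K2") %in% nn$node_id))   # annotated neighbors excluded
  expect_true(all(diff(nn$similarity) <= 0))
  all_nn <- nearest_unknown_neighbors(net, "K", k = 100)
  expect_equal(sort(all_nn$node_id), c("U_a", "U_b", "U_c"))
  expect_error(nearest_unknown_neighbors(net, "nope"), "unknown node")
})

test_that("condition statistics summarize enrichment and quantification", {
  mt <- rbind(make_mid_table(list(N = c(0.8, 0.2)), conditions = "A",
                             quantification = 100),
              make_mid_table(list(N = c(0.6, 0.4)), conditions = "B",
                             quantification = 300))
  mt <- mid_table(mt)
  st <- condition_stats(mt)
  expect_equal(st$mean_enrichment, 0.3)
  expect_equal(st$sd_enrichment, 0.1414, tolerance = 1e-3)
  expect_equal(st$mean_quantification, 200)
  expect_equal(st$n_records, 2)

  one <- condition_stats(make_mid_table(list(N = c(0.8, 0.2))))
  expect_equal(one$sd_enrichment, 0)
})
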