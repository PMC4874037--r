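star_graph <- function(n_leaves) {
  nodes <- c("hub", sprintf("L%d", seq_len(n_leaves)))
  pathway_graph(nodes, cbind(rep("hub", n_leaves), nodes[-1L]))
}

gene_table_for <- function(ids)
  data.frame(pathway_id = ids, rank = seq_along(ids),
             stringsAsFactors = FALSE)

test_that("top-fraction labelling flags the right counts", {
  ids <- sprintf("P%02d", 1:40)
  g <- pathway_graph(ids, cbind(ids[1:39], ids[2:40]))
  tab <- gene_table_for(ids)
  # 20 interacting pathways at top_frac 0.5 -> exactly 10 flagged
  lab <- suppressMessages(label_enriched(g, ids[11:30], tab, 0.5))
  expect_equal(sum(lab[ids[11:30]]), 10L)
  # the 10 best-ranked of the interacting set are the flagged ones
  expect_true(all(lab[ids[11:20]]))
  # top_frac = 1 flags every interacting pathway
  lab1 <- label_enriched(g, ids[11:30], tab, 1)
  expect_equal(sum(lab1[ids[11:30]]), 20L)
  # ceiling rule: 5 interacting at 0.5 -> 3
  lab5 <- label_enriched(g, ids[1:5], tab, 0.5)
  expect_equal(sum(lab5[ids[1:5]]), 3L)
  # labels are total over the graph nodes
  expect_false(anyNA(lab))
  expect_message(label_enriched(g, character(), tab, 0.5), "empty")
})

test_that("enriched neighbor counts come from the neighborhood only", {
  g <- star_graph(5)
  labs <- stats::setNames(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
                          g$nodes)  # hub + 3 leaves enriched
  expect_equal(enriched_neighbor_count(g, labs, "hub"), 3L)
  expect_equal(enriched_neighbor_count(g, labs, "L5"),
               1L)  # its only neighbor is the (enriched) hub
  labs[] <- FALSE
  expect_equal(enriched_neighbor_count(g, labs, "hub"), 0L)
  labs[] <- TRUE
  expect_equal(enriched_neighbor_count(g, labs, "hub"), 5L)
  expect_error(enriched_neighbor_count(g, labs, "nope"), "unknown")
})

test_that("randomization preserves the degree sequence exactly", {
  # the triangle is rigid: no admissible swap exists
  tri <- pathway_graph(c("A", "B", "C"),
                       rbind(c("A", "B"), c("A", "C"), c("B", "C")))
  expect_identical(randomize_graph(tri, seed = 1)$edges, tri$edges)
  # random graphs over many seeds
  set.seed(5)
  for (r in 1:20) {
    n <- sample(6:12, 1)
    nodes <- sprintf("N%02d", seq_len(n))
    pairs <- t(combn(nodes, 2))
    pick <- sample(nrow(pairs), n + 3)
    g <- pathway_graph(nodes, pairs[pick, ])
    rg <- randomize_graph(g, seed = 100 + r)
    expect_identical(graph_degree(rg), graph_degree(g))
    expect_identical(sort(rg$nodes), sort(g$nodes))
  }
})

test_that("the swap chain actually moves on non-rigid graphs", {
  set.seed(11)
  nodes <- sprintf("N%d", 1:8)
  pairs <- t(combn(nodes, 2))
  g <- pathway_graph(nodes, pairs[sample(nrow(pairs), 10), ])
  moved <- vapply(1:40, function(s) {
    rg <- randomize_graph(g, seed = s)
    !identical(rg$edges, g$edges)
  }, logical(1))
  expect_gte(mean(moved), 0.95)
})

test_that("permutation p-values obey their structural bounds", {
  g <- star_graph(4)
  labs <- stats::setNames(rep(TRUE, 5), g$nodes)
  # all neighbors enriched: N_obs = degree, nothing can exceed it
  res <- permutation_test(g, labs, "hub", B = 50, seed = 3)
  expect_equal(res$N_obs, res$degree)
  expect_equal(res$P_strict, 0)
  # B = 1 gives p in {0, 1}
  res1 <- permutation_test(g, labs, "L1", B = 1, seed = 3)
  expect_true(res1$P_strict %in% c(0, 1))
  # strict vs >= estimators differ as documented
  expect_true(all(res$P_strict <= res$P_geq))
  # bit-for-bit reproducibility
  labs2 <- stats::setNames(c(TRUE, TRUE, FALSE, TRUE, FALSE), g$nodes)
  a <- permutation_test(g, labs2, c("hub", "L1"), B = 200, seed = 9)
  b <- permutation_test(g, labs2, c("hub", "L1"), B = 200, seed = 9)
  expect_identical(a, b)
  expect_identical(attr(a, "counts"), attr(b, "counts"))
})

test_that("Monte-Carlo p matches exhaustive enumeration on a toy graph", {
  # 5-node graph: exact reference over every simple graph realizing the
  # degree vector
  cat5 <- graph_catalog(5)
  nodes <- sprintf("P%d", 1:5)
  edges <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(2, 5))
  g <- pathway_graph(nodes, matrix(nodes[edges], ncol = 2))
  labels <- stats::setNames(c(TRUE, FALSE, TRUE, FALSE, TRUE), nodes)
  degv <- unname(graph_degree(g)[nodes])
  j <- 2L
  exact <- exact_neighbor_counts(cat5, degv, unname(labels), j)
  n_obs <- enriched_neighbor_count(g, labels, nodes[j])
  p_exact <- mean(exact > n_obs)
  res <- permutation_test(g, labels, nodes[j], B = 4000, n_swaps = 200,
                          seed = 21)
  se <- sqrt(p_exact * (1 - p_exact) / 4000)
  expect_lt(abs(res$P_strict - p_exact), 3 * se + 1e-12)
})
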