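#' Flag enriched pathways for the neighbor permutation test
#'
#' Pathways in `interacting` are re-ranked among themselves by their
#' gene-layer rank and the top `ceil(top_frac * |interacting|)` are flagged
#' enriched (with 20 interacting pathways and `top_frac = 0.5`, exactly 10).
#' Every other graph node is labelled by the same rule applied to the
#' global gene ranking (top `ceil(top_frac * J)`), so that labels are total
#' and randomized graphs -- whose neighbor sets differ from the observed
#' one -- can always be scored. Labels are computed once from the observed
#' data and held fixed across random networks.
#'
#' @param graph a [pathway_graph()].
#' @param interacting pathway ids interacting with the nominated pathways.
#' @param gene_table gene-layer enrichment table (with `pathway_id`,
#'   `rank`).
#' @param top_frac fraction of pathways flagged, in `(0, 1]`.
#' @return named logical vector over `graph$nodes` with a `provenance`
#'   attribute describing the rule.
#' @export
label_enriched <- function(graph, interacting, gene_table, top_frac = 0.5) {
  if (top_frac <= 0 || top_frac > 1) fail("top_frac must be in (0, 1]")
  bad <- setdiff(interacting, gene_table$pathway_id)
  if (length(bad))
    fail("interacting pathway(s) missing from the gene table: %s",
         paste(bad, collapse = ", "))
  labels <- stats::setNames(rep(FALSE, length(graph$nodes)), graph$nodes)
  if (!length(interacting)) {
    note("label_enriched: empty interacting set, all labels FALSE")
  } else {
    sub <- gene_table[gene_table$pathway_id %in% interacting, ]
    local_rank <- rank_pathways(sub$rank, numeric(nrow(sub)), sub$pathway_id)
    k <- ceiling(top_frac * nrow(sub))
    labels[sub$pathway_id[local_rank <= k]] <- TRUE
  }
  k_glob <- ceiling(top_frac * nrow(gene_table))
  glob <- gene_table$pathway_id[gene_table$rank <= k_glob]
  others <- setdiff(intersect(graph$nodes, gene_table$pathway_id),
                    interacting)
  labels[others] <- others %in% glob
  attr(labels, "provenance") <- sprintf(
    "interacting set re-ranked, top %.0f%% flagged; remaining nodes by the same rule on the global gene ranking",
    100 * top_frac)
  labels
}

#' Count enriched neighbors of a pathway
#'
#' @param graph a [pathway_graph()].
#' @param labels named logical vector over the graph nodes (see
#'   [label_enriched()]).
#' @param j a pathway id (its own label is irrelevant).
#' @return integer count.
#' @export
enriched_neighbor_count <- function(graph, labels, j) {
  nb <- graph_neighbors(graph, j)
  sum(labels[nb])
}

#' Degree-preserving graph randomization
#'
#' Runs a double-edge-swap Markov chain: each attempt picks two edges
#' `(a-b, c-d)` with four distinct endpoints and rewires them to
#' `(a-c, b-d)` or `(a-d, b-c)` unless a duplicate edge would result. The
#' degree sequence (and node set) is exactly preserved. Graphs with fewer
#' than 2 edges are returned unchanged.
#'
#' @param graph a [pathway_graph()].
#' @param n_swaps number of swap attempts (default `10 * |E|`, a standard
#'   mixing heuristic).
#' @param seed optional RNG seed; if `NULL`, the current RNG stream is
#'   used.
#' @return a [pathway_graph()] with the same nodes and degree sequence.
#' @export
randomize_graph <- function(graph, n_swaps = NULL, seed = NULL) {
  m <- nrow(graph$edges)
  if (m < 2L) {
    note("randomize_graph: fewer than 2 edges, graph unchanged")
    return(graph)
  }
  n_swaps <- check_count(n_swaps %||% (10L * m), "n_swaps")
  ei <- matrix(match(graph$edges, graph$nodes), ncol = 2L)
  run <- function() edge_swap_cpp(ei, length(graph$nodes), n_swaps)
  out <- if (is.null(seed)) run() else with_seed(seed, run())
  pathway_graph(graph$nodes,
                matrix(graph$nodes[out], ncol = 2L))
}

#' Network-based permutation test for nominated pathways
#'
#' For each nominated pathway `j`, compares its observed enriched-neighbor
#' count `N(j)` against counts `N(j, b)` on `B` independent
#' degree-preserving random networks (each a fresh swap chain from the
#' observed graph, seeded by `seed + b`), with the enrichment labels held
#' fixed. The reported p-value uses the strict inequality
#' `P(j) = #{b : N(j, b) > N(j)} / B`; the conventional add-one estimator
#' on `>=`, `P_geq = (1 + #{N(j, b) >= N(j)}) / (B + 1)`, is reported
#' alongside (strict `>` is anti-conservative by at most `1/B` relative to
#' `>=`).
#'
#' @param graph a [pathway_graph()].
#' @param labels named logical labels over the nodes ([label_enriched()]).
#' @param nominated pathway ids to test.
#' @param B number of random networks (default 10000).
#' @inheritParams randomize_graph
#' @param seed base RNG seed.
#' @return data.frame (`pathway_id`, `degree`, `N_obs`, `P_strict`,
#'   `P_geq`, `B`) with attributes `counts` (nominated x B matrix), `seed`,
#'   `n_swaps`, `top` (smallest-P pathway, ties broken by id).
#' @export
permutation_test <- function(graph, labels, nominated, B = 10000L,
                             n_swaps = NULL, seed = 1L) {
  check_count(B, "B", min = 1L)
  bad <- setdiff(nominated, graph$nodes)
  if (length(bad))
    fail("nominated pathway(s) not in the graph: %s",
         paste(bad, collapse = ", "))
  labels <- labels[graph$nodes]
  if (anyNA(labels)) fail("labels must cover every graph node")
  deg <- graph_degree(graph)[nominated]
  n_obs <- vapply(nominated, function(j)
    enriched_neighbor_count(graph, labels, j), integer(1L))
  m <- nrow(graph$edges)
  n_swaps <- check_count(n_swaps %||% max(1L, 10L * m), "n_swaps")
  ei <- matrix(match(graph$edges, graph$nodes), ncol = 2L)
  nom_idx <- match(nominated, graph$nodes)
  counts <- matrix(NA_integer_, length(nominated), B,
                   dimnames = list(nominated, NULL))
  # fresh chain per draw, seeded seed + b; RNG state restored afterwards
  labels <- as.logical(labels)
  nn <- length(graph$nodes)
  withr::with_preserve_seed({
    for (b in seq_len(B)) {
      set.seed(seed + b)
      counts[, b] <- swap_and_count_cpp(ei, nn, n_swaps, labels, nom_idx)
    }
  })
  p_strict <- rowMeans(counts > n_obs)
  p_geq <- (1 + rowSums(counts >= n_obs)) / (B + 1)
  out <- data.frame(pathway_id = nominated, degree = as.integer(deg),
                    N_obs = n_obs, P_strict = p_strict, P_geq = p_geq,
                    B = B, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "counts") <- counts
  attr(out, "seed") <- seed
  attr(out, "n_swaps") <- n_swaps
  attr(out, "top") <- if (nrow(out))
    out$pathway_id[order(out$P_strict, out$pathway_id)][1L] else NA_character_
  out
}
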