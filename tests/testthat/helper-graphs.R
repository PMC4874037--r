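# Exhaustive enumeration oracle for the degree-preserving permutation test.
# All labelled simple graphs on n nodes are indexed by the subsets of the
# choose(n, 2) possible edges; this is the independent reference against
# which the Monte-Carlo swap chain is checked.

graph_catalog <- function(n) {
  pairs <- combn(n, 2L)
  P <- ncol(pairs)
  S <- 2L^P
  present <- matrix(FALSE, S, P)
  for (p in seq_len(P))
    present[, p] <- bitwAnd(seq_len(S) - 1L, bitwShiftL(1L, p - 1L)) > 0L
  inc <- matrix(0L, P, n)
  inc[cbind(seq_len(P), pairs[1L, ])] <- 1L
  inc[cbind(seq_len(P), pairs[2L, ])] <- 1L
  list(n = n, pairs = pairs, present = present, deg = present %*% inc)
}

catalog_edges <- function(cat, row)
  t(cat$pairs[, cat$present[row, ], drop = FALSE])

graph_is_connected <- function(edges, n) {
  if (nrow(edges) == 0L) return(n == 1L)
  seen <- rep(FALSE, n)
  seen[1L] <- TRUE
  queue <- 1L
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    nb <- c(edges[edges[, 1L] == v, 2L], edges[edges[, 2L] == v, 1L])
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  all(seen)
}

# Exact distribution of the enriched-neighbor count of node j over all
# simple graphs realizing the exact per-node degree vector.
exact_neighbor_counts <- function(cat, degvec, labels, j) {
  hit <- rowSums(cat$deg == matrix(degvec, nrow(cat$deg), cat$n,
                                   byrow = TRUE)) == cat$n
  w <- as.integer((cat$pairs[1L, ] == j & labels[cat$pairs[2L, ]]) |
                    (cat$pairs[2L, ] == j & labels[cat$pairs[1L, ]]))
  as.vector(cat$present[hit, , drop = FALSE] %*% w)
}

# One representative labelled connected graph per distinct sorted degree
# sequence, for 3 <= n <= max_n.
connected_degree_class_reps <- function(max_n) {
  reps <- list()
  for (n in 3:max_n) {
    cat_n <- graph_catalog(n)
    conn <- vapply(seq_len(nrow(cat_n$present)), function(r) {
      sum(cat_n$present[r, ]) >= n - 1L &&
        graph_is_connected(catalog_edges(cat_n, r), n)
    }, logical(1L))
    key <- apply(t(apply(cat_n$deg[conn, , drop = FALSE], 1L, sort)), 1L,
                 paste, collapse = ",")
    rows <- which(conn)[!duplicated(key)]
    reps[[length(reps) + 1L]] <- list(n = n, catalog = cat_n, rows = rows)
  }
  reps
}
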