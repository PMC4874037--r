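#' Pathway definitions
#'
#' A `pathway_set` stores, per pathway id, a display name plus gene and
#' metabolite member sets. Pathways with no members in either layer are
#' dropped with a warning.
#'
#' @param gene_sets named list of character vectors (pathway id -> gene
#'   members); may be `NULL`.
#' @param metabolite_sets named list of character vectors (pathway id ->
#'   metabolite members); may be `NULL`.
#' @param names optional named character vector of display names.
#' @return an object of class `pathway_set` with components `ids`, `names`,
#'   `gene_members`, `metabolite_members`.
#' @export
pathway_set <- function(gene_sets = NULL, metabolite_sets = NULL,
                        names = NULL) {
  ids <- union(base::names(gene_sets %||% list()),
               base::names(metabolite_sets %||% list()))
  if (anyDuplicated(base::names(gene_sets)) ||
      anyDuplicated(base::names(metabolite_sets)))
    fail("duplicate pathway id(s) in member lists")
  gm <- lapply(stats::setNames(ids, ids),
               function(i) unique(as.character(gene_sets[[i]])))
  mm <- lapply(stats::setNames(ids, ids),
               function(i) unique(as.character(metabolite_sets[[i]])))
  empty <- ids[lengths(gm) + lengths(mm) == 0L]
  if (length(empty)) {
    warning(sprintf("dropping pathway(s) with no members: %s",
                    paste(empty, collapse = ", ")), call. = FALSE)
    ids <- setdiff(ids, empty)
    gm <- gm[ids]; mm <- mm[ids]
  }
  if (length(ids) < 2L) fail("a pathway_set needs at least 2 pathways")
  nm <- stats::setNames(ids, ids)
  if (!is.null(names)) nm[base::names(names)] <- names
  structure(list(ids = ids, names = nm[ids], gene_members = gm,
                 metabolite_members = mm),
            class = "pathway_set")
}

#' @export
length.pathway_set <- function(x) length(x$ids)

#' @export
print.pathway_set <- function(x, ...) {
  cat(sprintf("pathway_set: %d pathways (%d with genes, %d with metabolites)\n",
              length(x$ids), sum(lengths(x$gene_members) > 0),
              sum(lengths(x$metabolite_members) > 0)))
  invisible(x)
}

#' Read and write GMT pathway membership files
#'
#' Standard GMT dialect: `name<TAB>description<TAB>member1<TAB>member2...`.
#' Parsing goes through [fgsea::gmtPathways()]; duplicate pathway names are
#' an error, empty pathways are dropped with a warning by [pathway_set()].
#'
#' @param path file path.
#' @return `read_gmt()` returns a named list of member character vectors.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  dup <- names(sets)[duplicated(names(sets))]
  if (length(dup))
    fail("%s: duplicate pathway name(s): %s", path,
         paste(unique(dup), collapse = ", "))
  lapply(sets, function(x) x[nzchar(x)])
}

#' @rdname read_gmt
#' @param sets named list of member vectors.
#' @param descriptions optional character vector of descriptions (default
#'   `"na"`).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  desc <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write reaction lists
#'
#' TSV with header `reaction_id<TAB>substrates<TAB>products`; substrates and
#' products are `;`-joined metabolite ids.
#'
#' @param path file path.
#' @return `read_reactions()` returns a data.frame with character columns
#'   `reaction_id`, `substrates`, `products` (still `;`-joined).
#' @export
read_reactions <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, fill = FALSE,
                   colClasses = "character")
  need <- c("reaction_id", "substrates", "products")
  if (!all(need %in% names(df)))
    fail("%s: expected columns %s", path, paste(need, collapse = ", "))
  df[need]
}

#' @rdname read_reactions
#' @param reactions data.frame as returned by `read_reactions()`.
#' @export
write_reactions <- function(reactions, path) {
  write_tsv(reactions[c("reaction_id", "substrates", "products")], path)
}

split_members <- function(x) strsplit(as.character(x), ";", fixed = TRUE)

#' Build the metabolite reaction network
#'
#' Draws one undirected edge per distinct substrate-product pair across all
#' reactions: for a reaction with substrates S and products P, edges connect
#' every s in S to every p in P. Substrate-substrate and product-product
#' pairs are never edges, and a metabolite appearing on both sides of the
#' same reaction yields no self-loop. An optional exclusion list removes
#' currency metabolites (e.g. water, ATP) from edge construction entirely.
#'
#' @param reactions data.frame with columns `reaction_id`, `substrates`,
#'   `products` (`;`-joined ids).
#' @param weights optional numeric vector of positive per-reaction edge
#'   weights (default 1); carried on edges but unused by enrichment.
#' @param exclude character vector of metabolite ids to drop before building
#'   edges (default none).
#' @return an object of class `reaction_network`: list with `nodes`
#'   (character) and `edges` (data.frame `from`, `to`, `weight`).
#' @export
build_metabolite_network <- function(reactions, weights = NULL,
                                     exclude = character()) {
  if (is.null(reactions) || nrow(reactions) == 0L) {
    return(structure(list(nodes = character(),
                          edges = data.frame(from = character(),
                                             to = character(),
                                             weight = numeric())),
                     class = "reaction_network"))
  }
  subs <- split_members(reactions$substrates)
  prods <- split_members(reactions$products)
  w <- weights %||% rep(1, nrow(reactions))
  if (any(w <= 0)) fail("edge weights must be positive")
  nodes <- character(0)
  from <- to <- character(0)
  ew <- numeric(0)
  for (i in seq_len(nrow(reactions))) {
    s <- setdiff(subs[[i]][nzchar(subs[[i]])], exclude)
    p <- setdiff(prods[[i]][nzchar(prods[[i]])], exclude)
    if (length(subs[[i]][nzchar(subs[[i]])]) == 0L ||
        length(prods[[i]][nzchar(prods[[i]])]) == 0L)
      fail("malformed reaction %s: needs at least one substrate and one product",
           reactions$reaction_id[i])
    nodes <- c(nodes, s, p)
    if (length(s) && length(p)) {
      pair <- expand.grid(s = s, p = p, stringsAsFactors = FALSE)
      pair <- pair[pair$s != pair$p, , drop = FALSE]
      from <- c(from, pair$s)
      to <- c(to, pair$p)
      ew <- c(ew, rep(w[i], nrow(pair)))
    }
  }
  if (length(from)) {
    a <- pmin(from, to)
    b <- pmax(from, to)
    keep <- a != b & !duplicated(paste(a, b, sep = "\r"))
    edges <- data.frame(from = a[keep], to = b[keep], weight = ew[keep],
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric())
  }
  structure(list(nodes = sort(unique(nodes)), edges = edges),
            class = "reaction_network")
}

#' Restrict a reaction network to a set of metabolites
#'
#' Keeps only nodes in `keep` and edges with both endpoints kept; used to
#' align the network with the metabolites that survive preprocessing.
#' @param network a `reaction_network`.
#' @param keep character vector of metabolite ids to retain.
#' @export
subset_network <- function(network, keep) {
  e <- network$edges
  e <- e[e$from %in% keep & e$to %in% keep, , drop = FALSE]
  rownames(e) <- NULL
  structure(list(nodes = intersect(network$nodes, keep), edges = e),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("reaction_network: %d metabolites, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Build the pathway-interaction network
#'
#' Two pathways X != Y are connected iff (a) some reaction-network edge has
#' one endpoint among X's metabolite members and the other among Y's, or
#' (b) some pair in `extra_gene_links` has one gene in X and the other in Y.
#' Shared members alone never create an edge: with heavily overlapping
#' pathway definitions, membership-overlap edges would make the graph close
#' to complete and void the degree-preserving permutation test downstream.
#'
#' @param pathways a [pathway_set()].
#' @param network a [build_metabolite_network()] result; may be `NULL`.
#' @param extra_gene_links optional 2-column data.frame/matrix of curated
#'   gene-gene interaction pairs.
#' @return object of class `pathway_graph`: list with `nodes` (all pathway
#'   ids; isolated pathways permitted) and `edges` (2-column character
#'   matrix, canonical order).
#' @export
build_pathway_graph <- function(pathways, network = NULL,
                                extra_gene_links = NULL) {
  nodes <- pathways$ids
  from <- to <- character(0)
  link_pairs <- function(mem_a, mem_b, members) {
    # pathways containing each endpoint of one molecular interaction
    pa <- nodes[vapply(members, function(m) mem_a %in% m, logical(1L))]
    pb <- nodes[vapply(members, function(m) mem_b %in% m, logical(1L))]
    if (!length(pa) || !length(pb)) return(NULL)
    g <- expand.grid(a = pa, b = pb, stringsAsFactors = FALSE)
    g[g$a != g$b, , drop = FALSE]
  }
  if (!is.null(network) && nrow(network$edges)) {
    for (i in seq_len(nrow(network$edges))) {
      g <- link_pairs(network$edges$from[i], network$edges$to[i],
                      pathways$metabolite_members)
      if (!is.null(g) && nrow(g)) { from <- c(from, g$a); to <- c(to, g$b) }
    }
  }
  if (!is.null(extra_gene_links) && NROW(extra_gene_links)) {
    el <- as.matrix(extra_gene_links)
    for (i in seq_len(nrow(el))) {
      g <- link_pairs(el[i, 1L], el[i, 2L], pathways$gene_members)
      if (!is.null(g) && nrow(g)) { from <- c(from, g$a); to <- c(to, g$b) }
    }
  }
  pathway_graph(nodes, canonical_edges(cbind(from, to)))
}

#' Construct a pathway graph from nodes and edges
#'
#' @param nodes character vector of pathway ids.
#' @param edges 2-column character matrix of undirected edges; self-loops
#'   and duplicates are removed.
#' @export
pathway_graph <- function(nodes, edges) {
  edges <- canonical_edges(edges)
  bad <- setdiff(c(edges), nodes)
  if (length(bad))
    fail("edge endpoint(s) not in node set: %s", paste(bad, collapse = ", "))
  structure(list(nodes = as.character(nodes), edges = edges),
            class = "pathway_graph")
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("pathway_graph: %d pathways, %d interactions\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Degree and neighbors on a pathway graph
#' @param graph a [pathway_graph()].
#' @return `graph_degree()`: named integer vector over all nodes.
#' @export
graph_degree <- function(graph) {
  d <- stats::setNames(integer(length(graph$nodes)), graph$nodes)
  if (nrow(graph$edges)) {
    tab <- table(c(graph$edges[, 1L], graph$edges[, 2L]))
    d[names(tab)] <- as.integer(tab)
  }
  d
}

#' @rdname graph_degree
#' @param id a node id.
#' @export
graph_neighbors <- function(graph, id) {
  if (!id %in% graph$nodes) fail("unknown pathway id: %s", id)
  e <- graph$edges
  sort(unique(c(e[e[, 1L] == id, 2L], e[e[, 2L] == id, 1L])))
}

#' Read and write pathway graphs as edge-list TSV
#'
#' Layout `pathway_a<TAB>pathway_b`; isolated nodes are kept in a leading
#' comment-free node manifest column when written via the pipeline manifest,
#' so `read_pathway_graph()` takes the node set explicitly.
#' @param graph a [pathway_graph()].
#' @param path file path.
#' @export
write_pathway_graph <- function(graph, path) {
  df <- data.frame(pathway_a = graph$edges[, 1L],
                   pathway_b = graph$edges[, 2L])
  write_tsv(df, path)
}

#' @rdname write_pathway_graph
#' @param nodes node set (edge lists do not record isolated pathways).
#' @export
read_pathway_graph <- function(path, nodes) {
  df <- read.delim(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, fill = FALSE,
                   colClasses = "character")
  pathway_graph(nodes, as.matrix(df[c("pathway_a", "pathway_b")]))
}
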