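# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code with a temporary RNG seed
#'
#' Wrapper around [withr::with_seed()] so that every randomized operation in
#' the package draws from an explicit seed and leaves the caller's RNG state
#' untouched.
#' @noRd
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

# stop() with sprintf-style formatting and no call in the condition
fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

note <- function(fmt, ...) message(sprintf(fmt, ...))

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    fail("`%s` must be a single value in [0, 1], got %s", name,
         paste(format(x), collapse = ", "))
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x))
    fail("`%s` must be a single integer >= %d", name, min)
  invisible(as.integer(x))
}

# Canonicalize an undirected edge table: sorted endpoints, deduplicated,
# rows ordered. `edges` is a 2-column character matrix.
canonical_edges <- function(edges) {
  if (is.null(edges) || nrow(edges) == 0L) {
    return(matrix(character(), ncol = 2L,
                  dimnames = list(NULL, c("from", "to"))))
  }
  a <- pmin(edges[, 1L], edges[, 2L])
  b <- pmax(edges[, 1L], edges[, 2L])
  keep <- !duplicated(paste(a, b, sep = "\r")) & a != b
  a <- a[keep]; b <- b[keep]
  o <- order(a, b)
  matrix(c(a[o], b[o]), ncol = 2L, dimnames = list(NULL, c("from", "to")))
}

# Deterministic ranking used by both enrichment layers: ascending p-value,
# ties by descending |score|, then lexicographic id.  Returns an integer
# permutation of 1..length(p).
rank_pathways <- function(p, score, ids) {
  ord <- order(p, -abs(score), ids)
  r <- integer(length(p))
  r[ord] <- seq_along(ord)
  r
}

# write.table with the conventions used for all package TSV output
write_tsv <- function(df, path, row.names = FALSE) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = row.names,
              col.names = TRUE, na = "")
  invisible(path)
}
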