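#' Per-gene two-sample statistics
#'
#' Welch two-sample t statistic per gene, oriented class 2 minus class 1.
#' Genes with zero variance in both classes get statistic 0 with a warning.
#'
#' @param expression an [omics_matrix()] (gene layer, no missing values).
#' @param labels a [class_labels()] vector covering the samples.
#' @return named numeric vector of statistics with attributes `n1`, `n2`.
#' @export
gene_stats <- function(expression, labels) {
  cls <- align_labels(expression, labels)
  if (anyNA(expression)) fail("expression matrix contains missing values")
  z <- welch_t_cols(expression, matrix(as.numeric(cls == 2L), ncol = 1L),
                    warn_zero = TRUE)[, 1L]
  structure(stats::setNames(z, rownames(expression)),
            n1 = sum(cls == 1L), n2 = sum(cls == 2L))
}

# Vectorized Welch t for many class assignments at once.  `ind2` is an
# n x C matrix of 0/1 class-2 indicators; returns a G x C matrix.
welch_t_cols <- function(X, ind2, warn_zero = FALSE) {
  X <- unclass(X)
  n <- ncol(X)
  n2 <- colSums(ind2)
  n1 <- n - n2
  rs <- rowSums(X)
  rq <- rowSums(X^2)
  S2 <- X %*% ind2
  Q2 <- (X^2) %*% ind2
  M2 <- sweep(S2, 2L, n2, "/")
  M1 <- sweep(rs - S2, 2L, n1, "/")
  V2 <- sweep(Q2 - sweep(M2^2, 2L, n2, "*"), 2L, n2 - 1, "/")
  V1 <- sweep((rq - Q2) - sweep(M1^2, 2L, n1, "*"), 2L, n1 - 1, "/")
  V1[V1 < 0] <- 0  # guard tiny negative rounding
  V2[V2 < 0] <- 0
  se <- sqrt(sweep(V1, 2L, n1, "/") + sweep(V2, 2L, n2, "/"))
  t <- (M2 - M1) / se
  zero <- se == 0
  if (any(zero)) {
    if (warn_zero)
      warning(sprintf("%d gene(s) with zero variance in both classes; statistic set to 0",
                      sum(rowSums(zero) > 0)), call. = FALSE)
    t[zero] <- 0
  }
  t
}

#' The maxmean gene-set statistic
#'
#' With member statistics z over the m genes present,
#' `s_plus = sum(pmax(z, 0))/m` and `s_minus = sum(pmax(-z, 0))/m`; the
#' statistic is `s_plus` if `s_plus >= s_minus`, else `-s_minus`. On a set
#' of size one it is the identity.
#'
#' @param stats named numeric vector of per-gene statistics.
#' @param members character vector of member gene ids.
#' @return the maxmean statistic (length-1 numeric).
#' @export
maxmean <- function(stats, members) {
  z <- stats[intersect(members, names(stats))]
  if (!length(z)) fail("no member genes present in the statistics vector")
  s_plus <- sum(pmax(z, 0)) / length(z)
  s_minus <- sum(pmax(-z, 0)) / length(z)
  if (s_plus >= s_minus) s_plus else -s_minus
}

# all distinct assignments of n2 of n samples to class 2, as an n x C
# 0/1 indicator matrix (includes the observed assignment)
all_assignments <- function(n, n2) {
  idx <- combn(n, n2)
  ind <- matrix(0, n, ncol(idx))
  ind[cbind(as.vector(idx), rep(seq_len(ncol(idx)), each = n2))] <- 1
  ind
}

#' Gene-layer pathway enrichment (GSA)
#'
#' For each eligible pathway the maxmean statistic is restandardized
#' against a catalog of randomly drawn same-size gene sets: the score is
#' `s* = (s - mu_set) / sd_set` with `mu_set`, `sd_set` the catalog mean and
#' SD (recomputed under every permutation from the same catalog sets).
#' Significance is assessed by class-label permutation,
#' `p = (1 + #{|s*_perm| >= |s*_obs|}) / (n_perm + 1)`; when the number of
#' distinct class assignments is at most `n_perm` they are enumerated
#' exhaustively instead and `p` is the exact proportion (the observed
#' assignment counts itself, so p is never 0). Ranks are ascending in
#' p-value with ties broken by descending `|s*|` then pathway id.
#'
#' @param expression preprocessed gene [omics_matrix()].
#' @param labels a [class_labels()] vector.
#' @param pathways a [pathway_set()].
#' @param n_perm number of label permutations (>= 100).
#' @param seed RNG seed for permutations and catalog draws.
#' @param n_catalog random same-size gene sets per distinct pathway size.
#' @param min_genes minimum member genes present for eligibility.
#' @return data.frame (`pathway_id`, `layer`, `score`, `p_value`, `rank`)
#'   over eligible pathways, with attributes `n_perm_used`, `exhaustive`,
#'   `ineligible` (ids).
#' @export
gsa_enrich <- function(expression, labels, pathways, n_perm = 1000L,
                       seed = 1L, n_catalog = 500L, min_genes = 5L) {
  check_count(n_perm, "n_perm", min = 100L)
  cls <- align_labels(expression, labels)
  X <- unclass(expression)
  genes <- rownames(X)
  members <- lapply(pathways$gene_members, intersect, genes)
  elig <- names(members)[lengths(members) >= max(1L, min_genes)]
  if (!length(elig)) fail("no pathway is eligible on the gene layer")
  members <- members[elig]
  sizes <- lengths(members)

  n <- ncol(X)
  n2 <- sum(cls == 2L)
  n_assign <- choose(n, n2)
  exhaustive <- n_assign <= n_perm
  obs_ind <- matrix(as.numeric(cls == 2L), ncol = 1L)

  res <- with_seed(seed, {
    if (exhaustive) {
      note("gsa_enrich: enumerating all %d distinct class assignments",
           n_assign)
      perm_ind <- all_assignments(n, n2)
    } else {
      perm_ind <- matrix(0, n, n_perm)
      for (b in seq_len(n_perm)) perm_ind[sample.int(n, n2), b] <- 1
    }
    # catalog of random same-size sets, shared across permutations
    usizes <- sort(unique(sizes))
    cat_members <- lapply(usizes, function(m) {
      lapply(seq_len(n_catalog), function(i) sample(genes, m))
    })
    list(perm_ind = perm_ind, usizes = usizes, cat_members = cat_members)
  })

  Z <- welch_t_cols(X, cbind(obs_ind, res$perm_ind))
  all_sets <- c(members, unlist(res$cat_members, recursive = FALSE))
  set_sizes <- lengths(all_sets)
  M <- sparseMatrix(i = rep(seq_along(all_sets), set_sizes),
                    j = match(unlist(all_sets), genes),
                    x = 1, dims = c(length(all_sets), length(genes)))
  SP <- as.matrix(M %*% pmax(Z, 0)) / set_sizes
  SM <- as.matrix(M %*% pmax(-Z, 0)) / set_sizes
  SC <- ifelse(SP >= SM, SP, -SM)

  J <- length(elig)
  cat_rows <- J + seq_len(n_catalog * length(res$usizes))
  cat_size <- rep(res$usizes, each = n_catalog)
  sstar <- matrix(NA_real_, J, ncol(SC))
  for (m in res$usizes) {
    block <- SC[cat_rows[cat_size == m], , drop = FALSE]
    mu <- colMeans(block)
    sdv <- sqrt(colMeans(block^2) - mu^2) *
      sqrt(nrow(block) / (nrow(block) - 1))
    sdv[sdv < 1e-12] <- 1e-12
    rows <- which(sizes == m)
    sstar[rows, ] <- sweep(sweep(SC[rows, , drop = FALSE], 2L, mu, "-"),
                           2L, sdv, "/")
  }

  s_obs <- sstar[, 1L]
  s_perm <- abs(sstar[, -1L, drop = FALSE])
  if (exhaustive) {
    # the enumerated columns include the observed assignment, so p >= 1/C
    p <- rowMeans(s_perm >= abs(s_obs))
    n_perm_used <- n_assign
  } else {
    p <- (1 + rowSums(s_perm >= abs(s_obs))) / (n_perm + 1)
    n_perm_used <- n_perm
  }

  out <- data.frame(pathway_id = elig, layer = "gene", score = s_obs,
                    p_value = p,
                    rank = rank_pathways(p, s_obs, elig),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_perm_used") <- n_perm_used
  attr(out, "exhaustive") <- exhaustive
  attr(out, "ineligible") <- setdiff(pathways$ids, elig)
  out
}
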