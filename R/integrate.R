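#' Bootstrap the pathway ranking of one omics layer
#'
#' Draws `n_boot` stratified bootstrap resamples (samples drawn with
#' replacement within each class, class sizes preserved), re-runs the
#' supplied enrichment function on every resample, and records each
#' pathway's rank. Resamples in which a class collapses to a single
#' distinct sample are redrawn (counted in the `redraws` attribute), and an
#' enrichment failure on a resample triggers up to 10 redraws before
#' aborting.
#'
#' @param data an [omics_matrix()] for the layer.
#' @param labels a [class_labels()] vector.
#' @param enrich_fn `function(values, cls, seed)` returning a data.frame
#'   with columns `pathway_id` and `rank` (see [gsa_enrich()],
#'   [netgsa_enrich()]); `cls` is an integer vector of classes in column
#'   order.
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed RNG seed; resample `b` passes `seed + b` to `enrich_fn`.
#' @return data.frame (`pathway_id`, `R`, `S`): mean and sample SD of the
#'   rank over the `n_boot` resamples; attributes `n_boot`, `seed`,
#'   `redraws`, `rank_matrix`.
#' @export
bootstrap_rankings <- function(data, labels, enrich_fn, n_boot = 1000L,
                               seed = 1L) {
  check_count(n_boot, "n_boot", min = 2L)
  cls <- align_labels(data, labels)
  idx1 <- which(cls == 1L)
  idx2 <- which(cls == 2L)
  redraws <- 0L
  draws <- with_seed(seed, {
    lapply(seq_len(n_boot), function(b) {
      repeat {
        i1 <- sample(idx1, length(idx1), replace = TRUE)
        i2 <- sample(idx2, length(idx2), replace = TRUE)
        if (length(unique(i1)) > 1L && length(unique(i2)) > 1L)
          return(c(i1, i2))
        redraws <<- redraws + 1L
      }
    })
  })
  if (redraws > 0L) note("bootstrap_rankings: %d degenerate resample(s) redrawn",
                         redraws)
  X <- unclass(data)
  cls_b <- rep(c(1L, 2L), c(length(idx1), length(idx2)))
  ranks <- NULL
  ids <- NULL
  for (b in seq_len(n_boot)) {
    idx <- draws[[b]]
    res <- NULL
    for (attempt in 0:10) {
      use <- if (attempt == 0L) idx else with_seed(seed + n_boot + 7919L * b + attempt, {
        repeat {
          i1 <- sample(idx1, length(idx1), replace = TRUE)
          i2 <- sample(idx2, length(idx2), replace = TRUE)
          if (length(unique(i1)) > 1L && length(unique(i2)) > 1L)
            break
        }
        c(i1, i2)
      })
      Yb <- X[, use, drop = FALSE]
      colnames(Yb) <- make.unique(colnames(Yb))
      res <- tryCatch(enrich_fn(Yb, cls_b, seed + b), error = function(e) e)
      if (!inherits(res, "error")) break
    }
    if (inherits(res, "error"))
      fail("enrichment failed on bootstrap resample %d after 10 redraws: %s",
           b, conditionMessage(res))
    if (is.null(ids)) {
      ids <- res$pathway_id
      ranks <- matrix(NA_real_, length(ids), n_boot, dimnames = list(ids))
    }
    if (!identical(res$pathway_id, ids))
      fail("pathway set changed across bootstrap resamples")
    ranks[, b] <- res$rank
  }
  out <- data.frame(pathway_id = ids, R = rowMeans(ranks),
                    S = apply(ranks, 1L, sd), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_boot") <- n_boot
  attr(out, "seed") <- seed
  attr(out, "redraws") <- redraws
  attr(out, "rank_matrix") <- ranks
  out
}

#' Combined integrative pathway score
#'
#' `(J + 1 - Rg) / max(Sg, s_floor) + (J + 1 - Rm) / max(Sm, s_floor)`:
#' the variability-normalized reversed-rank sum over the gene and
#' metabolite layers (for 87 pathways the reversal constant is 88). Higher
#' means more enriched. The published form of the equation is
#' typographically ambiguous; the alternative reading
#' `(J + 1) - R/max(S, s_floor)` per layer is available as
#' `variant = "reversed_minus_ratio"` for sensitivity analysis.
#'
#' @param Rg,Sg bootstrap mean and SD of the gene-layer rank.
#' @param Rm,Sm bootstrap mean and SD of the metabolite-layer rank.
#' @param J number of ranked pathways.
#' @param s_floor lower bound applied to the rank SDs (default 0.5, half a
#'   rank unit) so constant ranks do not divide by zero.
#' @param variant parenthesization of the score (see above).
#' @return numeric vector of combined scores.
#' @export
combined_score <- function(Rg, Sg, Rm, Sm, J, s_floor = 0.5,
                           variant = c("reversed_over_sd",
                                       "reversed_minus_ratio")) {
  variant <- match.arg(variant)
  if (s_floor <= 0) fail("s_floor must be positive")
  if (any(Rg < 1 | Rg > J) || any(Rm < 1 | Rm > J))
    fail("mean ranks must lie in [1, J]")
  if (any(Sg < 0) || any(Sm < 0)) fail("rank SDs must be >= 0")
  sg <- pmax(Sg, s_floor)
  sm <- pmax(Sm, s_floor)
  if (variant == "reversed_over_sd") {
    (J + 1 - Rg) / sg + (J + 1 - Rm) / sm
  } else {
    (J + 1 - Rg / sg) + (J + 1 - Rm / sm)
  }
}

# One-sided (upper) Grubbs p-value for the maximum of x.
grubbs_p <- function(x) {
  N <- length(x)
  s <- sd(x)
  if (s == 0) return(list(G = NA_real_, p = 1))
  G <- (max(x) - mean(x)) / s
  ub <- (N - 1)^2 / N
  if (G^2 >= ub) return(list(G = G, p = 0))
  t2 <- N * (N - 2) * G^2 / ((N - 1)^2 - N * G^2)
  p <- min(1, N * stats::pt(sqrt(t2), df = N - 2, lower.tail = FALSE))
  list(G = G, p = p)
}

#' Nominate outlier pathways from combined scores
#'
#' Iterative one-sided Grubbs ("normal") outlier test on the combined
#' scores: while the maximal score is a significant upper outlier at level
#' `alpha`, it is flagged and removed, up to `max_outliers` flags. Flagged
#' pathways receive `is_top = TRUE` and their Grubbs p-value; a zero score
#' SD yields no outliers.
#'
#' @param scores data.frame with columns `pathway_id` and `score` (see
#'   [combine_layers()]).
#' @param alpha significance level (default 0.03).
#' @param max_outliers cap on the number of iterative flags (default 10).
#' @return the input with columns `grubbs_p` (NA for unflagged) and
#'   `is_top` added.
#' @export
outlier_pathways <- function(scores, alpha = 0.03, max_outliers = 10L) {
  if (nrow(scores) < 4L) fail("need at least 4 pathways for the outlier test")
  if (alpha <= 0 || alpha >= 1) fail("alpha must be in (0, 1)")
  scores$grubbs_p <- NA_real_
  scores$is_top <- FALSE
  active <- seq_len(nrow(scores))
  while (length(active) >= 4L && sum(scores$is_top) < max_outliers) {
    g <- grubbs_p(scores$score[active])
    if (is.na(g$G)) {
      note("outlier_pathways: zero score SD, no outliers")
      break
    }
    if (g$p >= alpha) break
    imax <- active[which.max(scores$score[active])]
    scores$grubbs_p[imax] <- g$p
    scores$is_top[imax] <- TRUE
    active <- setdiff(active, imax)
  }
  scores
}

#' Combine two bootstrap rankings into the integrative score table
#'
#' @param boot_gene,boot_metab [bootstrap_rankings()] results for the gene
#'   and metabolite layers; must cover the same pathways.
#' @inheritParams combined_score
#' @inheritParams outlier_pathways
#' @return data.frame (`pathway_id`, `R_gene`, `S_gene`, `R_metab`,
#'   `S_metab`, `score`, `grubbs_p`, `is_top`), ordered by decreasing
#'   score.
#' @export
combine_layers <- function(boot_gene, boot_metab, s_floor = 0.5,
                           alpha = 0.03, max_outliers = 10L,
                           variant = c("reversed_over_sd",
                                       "reversed_minus_ratio")) {
  if (!setequal(boot_gene$pathway_id, boot_metab$pathway_id))
    fail("layer pathway sets differ: only in gene layer: %s; only in metabolite layer: %s",
         paste(setdiff(boot_gene$pathway_id, boot_metab$pathway_id),
               collapse = ", "),
         paste(setdiff(boot_metab$pathway_id, boot_gene$pathway_id),
               collapse = ", "))
  m <- boot_metab[match(boot_gene$pathway_id, boot_metab$pathway_id), ]
  # rank scale: number of pathways, extended if the inputs are a subset of
  # a larger per-layer ranking (mean ranks can then exceed the row count)
  J <- max(nrow(boot_gene), ceiling(boot_gene$R), ceiling(m$R))
  tab <- data.frame(pathway_id = boot_gene$pathway_id,
                    R_gene = boot_gene$R, S_gene = boot_gene$S,
                    R_metab = m$R, S_metab = m$S,
                    stringsAsFactors = FALSE)
  tab$score <- combined_score(tab$R_gene, tab$S_gene, tab$R_metab,
                              tab$S_metab, J = J, s_floor = s_floor,
                              variant = match.arg(variant))
  tab <- outlier_pathways(tab, alpha = alpha, max_outliers = max_outliers)
  tab[order(-tab$score, tab$pathway_id), , drop = FALSE]
}

#' Concordance between the two layer rankings
#'
#' With per-pathway rank difference `d_j = rank_gene(j) - rank_metab(j)`,
#' the concordance is the fraction of pathways whose centered difference
#' lies within one standard deviation of all differences:
#' `#{j : |d_j - mean(d)| <= sd(d)} / J`. When both inputs are complete
#' rankings of the same set, `mean(d) = 0` and the centered and uncentered
#' readings coincide.
#'
#' @param rank_g,rank_m enrichment tables (data.frames with `pathway_id`
#'   and `rank`) over the same pathway set.
#' @return list of class `concordance_report`: `fraction`,
#'   `sd_of_differences`, `differences` (data.frame).
#' @export
concordance <- function(rank_g, rank_m) {
  if (!setequal(rank_g$pathway_id, rank_m$pathway_id))
    fail("pathway sets differ: only in first: %s; only in second: %s",
         paste(setdiff(rank_g$pathway_id, rank_m$pathway_id), collapse = ", "),
         paste(setdiff(rank_m$pathway_id, rank_g$pathway_id), collapse = ", "))
  m <- rank_m[match(rank_g$pathway_id, rank_m$pathway_id), ]
  d <- rank_g$rank - m$rank
  sdd <- sd(d)
  frac <- mean(abs(d - mean(d)) <= sdd)
  structure(list(fraction = frac, sd_of_differences = sdd,
                 differences = data.frame(pathway_id = rank_g$pathway_id,
                                          d = d, stringsAsFactors = FALSE)),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("concordance: %.1f%% of pathways within 1 SD (SD of rank differences = %.2f)\n",
              100 * x$fraction, x$sd_of_differences))
  invisible(x)
}
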