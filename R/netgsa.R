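#' Influence matrix of a metabolite network
#'
#' Propagates condition effects through the reaction network:
#' `Lambda = (I - rho * Abar)^-1` with `Abar` the row-normalized adjacency
#' (rows of isolated metabolites stay zero, so their rows of `Lambda` equal
#' the identity). `rho = 0` gives the identity matrix; any `rho` in
#' `[0, 1)` is admissible because the row-normalized adjacency has spectral
#' radius at most 1.
#'
#' @param network a [build_metabolite_network()] result.
#' @param rho propagation strength in `[0, 1)`.
#' @param metabolites optional ids to include as isolated nodes (typically
#'   the rownames of the metabolite matrix), so that metabolites absent from
#'   the reaction network keep identity rows instead of being dropped.
#' @return object of class `influence_matrix`: list with `Lambda`,
#'   `Lambda_inv` (`I - rho * Abar`, the exact inverse), `nodes` (sorted
#'   ids giving the row order), `rho`.
#' @export
influence_matrix <- function(network, rho, metabolites = NULL) {
  if (!is.numeric(rho) || length(rho) != 1L || is.na(rho) || rho < 0 ||
      rho >= 1)
    fail("rho must be in [0, 1)")
  nodes <- sort(union(network$nodes, metabolites %||% character()))
  p <- length(nodes)
  if (!p) fail("no metabolites to build an influence matrix over")
  A <- matrix(0, p, p, dimnames = list(nodes, nodes))
  if (nrow(network$edges)) {
    i <- match(network$edges$from, nodes)
    j <- match(network$edges$to, nodes)
    A[cbind(i, j)] <- network$edges$weight
    A[cbind(j, i)] <- network$edges$weight
  }
  rs <- rowSums(A)
  Abar <- A / ifelse(rs > 0, rs, 1)
  Linv <- diag(p) - rho * Abar
  Lambda <- solve(Linv)
  dimnames(Lambda) <- dimnames(Linv) <- list(nodes, nodes)
  structure(list(Lambda = Lambda, Lambda_inv = Linv, nodes = nodes,
                 rho = rho),
            class = "influence_matrix")
}

#' @export
print.influence_matrix <- function(x, ...) {
  cat(sprintf("influence_matrix: %d metabolites, rho = %.3g\n",
              length(x$nodes), x$rho))
  invisible(x)
}

# REML for the two-component model y_i ~ N(mu_k, sg2 * Lambda Lambda' +
# se2 * I), via the eigendecomposition G = U diag(d) U'.  In the rotated
# coordinates z = U'y each coordinate l is iid within class with variance
# v_l = sg2 * d_l + se2; the restricted -2 loglik is
# sum_l [(n-2) log v_l + RSS_l / v_l] up to a constant.
reml_components <- function(rss, d, n, sigma2_g = NULL, sigma2_e = NULL) {
  nf <- n - 2L
  crit <- function(sg2, se2) {
    v <- sg2 * d + se2
    if (any(v <= 0)) return(Inf)
    sum(nf * log(v) + rss / v)
  }
  mom <- function() {
    # E[RSS_l/(n-2)] = sg2 * d_l + se2: least squares on the coordinates
    w <- rss / nf
    if (stats::var(d) < 1e-12) {
      c(0, max(mean(w), 1e-12))
    } else {
      b <- stats::cov(d, w) / stats::var(d)
      a <- mean(w) - b * mean(d)
      c(max(b, 0), max(a, 1e-12))
    }
  }
  fixed_g <- !is.null(sigma2_g)
  fixed_e <- !is.null(sigma2_e)
  start <- mom()
  if (fixed_g && fixed_e) {
    est <- c(sigma2_g, sigma2_e)
    conv <- TRUE
  } else if (fixed_g || fixed_e) {
    obj <- if (fixed_g) function(x) crit(sigma2_g, x) else
      function(x) crit(x, sigma2_e)
    fit <- stats::nlminb(if (fixed_g) start[2L] else start[1L], obj,
                         lower = 1e-12)
    conv <- fit$convergence == 0
    est <- if (fixed_g) c(sigma2_g, fit$par) else c(fit$par, sigma2_e)
  } else {
    fit <- stats::nlminb(pmax(start, c(0, 1e-8)),
                         function(x) crit(x[1L], x[2L]),
                         lower = c(0, 1e-12))
    conv <- fit$convergence == 0
    est <- fit$par
  }
  if (!conv) {
    warning("REML did not converge; falling back to method-of-moments variance estimates",
            call. = FALSE)
    est <- mom()
    if (fixed_g) est[1L] <- sigma2_g
    if (fixed_e) est[2L] <- sigma2_e
  }
  # observed (expected) information of the free components
  v <- est[1L] * d + est[2L]
  xg <- d / v^2
  xe <- 1 / v^2
  info <- (nf / 2) * rbind(c(sum(d * xg), sum(xg)),
                           c(sum(xg), sum(xe)))
  free <- c(!fixed_g, !fixed_e)
  list(sigma2_g = est[1L], sigma2_e = est[2L], info = info, free = free,
       converged = conv)
}

#' Metabolite-layer pathway enrichment (network mixed model)
#'
#' Fits, per sample `i` in class `k`, `y_i = Lambda beta_k + Lambda gamma_i
#' + eps_i` with `gamma_i ~ N(0, sigma_g^2 I)` and `eps_i ~ N(0, sigma_e^2
#' I)`. Class means are estimated by generalized least squares (with an
#' invertible shared influence matrix this reduces exactly to
#' `beta_k = Lambda^-1 ybar_k`, independent of the covariance), and the
#' pathway contrast is `T_j = l_j' (beta_2 - beta_1) / SE` with
#' `l_j = Lambda' b_j` and `b_j` the unit-sum membership vector.
#'
#' Two SE estimators are available. `"profile"` (default) uses the pooled
#' within-class sample variance of the projected per-sample profile
#' `u_i = b_j' y_i`, which gives an exact t reference with `n - 2` degrees
#' of freedom under the model (and reduces identically to the classical
#' two-sample t-test on pathway-mean profiles when `rho = 0`). `"model"`
#' plugs REML variance components into
#' `SE^2 = (1/n1 + 1/n2) (sigma_g^2 ||Lambda' b_j||^2 + sigma_e^2
#' ||b_j||^2)` with Satterthwaite degrees of freedom; there the network
#' modulates the precision attributed to well-connected pathways. The
#' reasons for the default are discussed in the methods vignette.
#'
#' @param metabolites preprocessed metabolite [omics_matrix()] (no missing
#'   values); must contain every node of `influence`.
#' @param labels a [class_labels()] vector.
#' @param influence an [influence_matrix()].
#' @param pathways a [pathway_set()].
#' @param min_metabs minimum member metabolites present for eligibility.
#' @param se_method `"profile"` or `"model"`.
#' @param sigma2_g,sigma2_e optionally pin a variance component instead of
#'   estimating it by REML.
#' @param estimate_components estimate and report REML components even when
#'   `se_method = "profile"` does not need them (skipping them makes
#'   bootstrap resampling considerably faster).
#' @return data.frame (`pathway_id`, `layer`, `T`, `df`, `p_value`, `rank`)
#'   with attributes `sigma2_g`, `sigma2_e`, `se_method`, `ineligible`.
#' @export
netgsa_enrich <- function(metabolites, labels, influence, pathways,
                          min_metabs = 3L,
                          se_method = c("profile", "model"),
                          sigma2_g = NULL, sigma2_e = NULL,
                          estimate_components = TRUE) {
  se_method <- match.arg(se_method)
  cls <- align_labels(metabolites, labels)
  if (anyNA(metabolites)) fail("metabolite matrix contains missing values")
  absent <- setdiff(influence$nodes, rownames(metabolites))
  if (length(absent))
    fail("metabolite(s) in the influence matrix but not the data: %s",
         paste(head(absent, 5L), collapse = ", "))
  Y <- unclass(metabolites)[influence$nodes, , drop = FALSE]
  p <- nrow(Y)
  n <- ncol(Y)
  n1 <- sum(cls == 1L)
  n2 <- sum(cls == 2L)

  members <- lapply(pathways$metabolite_members, intersect, influence$nodes)
  elig <- names(members)[lengths(members) >= max(1L, min_metabs)]
  if (!length(elig)) fail("no pathway is eligible on the metabolite layer")
  members <- members[elig]
  J <- length(elig)
  B <- sparseMatrix(i = rep(seq_len(J), lengths(members)),
                    j = match(unlist(members), influence$nodes),
                    x = 1 / rep(lengths(members), lengths(members)),
                    dims = c(J, p))

  ybar1 <- rowMeans(Y[, cls == 1L, drop = FALSE])
  ybar2 <- rowMeans(Y[, cls == 2L, drop = FALSE])
  # GLS class means; with a shared invertible Lambda the GLS solution is
  # exact and covariance-free
  beta1 <- drop(influence$Lambda_inv %*% ybar1)
  beta2 <- drop(influence$Lambda_inv %*% ybar2)
  contrast <- drop(B %*% (influence$Lambda %*% (beta2 - beta1)))

  comp <- NULL
  if (estimate_components || se_method == "model") {
    G <- tcrossprod(influence$Lambda)
    eg <- eigen(G, symmetric = TRUE)
    Z <- crossprod(eg$vectors, Y)
    rss <- rowSums((Z[, cls == 1L, drop = FALSE] -
                      rowMeans(Z[, cls == 1L, drop = FALSE]))^2) +
      rowSums((Z[, cls == 2L, drop = FALSE] -
                 rowMeans(Z[, cls == 2L, drop = FALSE]))^2)
    comp <- reml_components(rss, eg$values, n, sigma2_g, sigma2_e)
  }

  kappa <- 1 / n1 + 1 / n2
  if (se_method == "profile") {
    U <- as.matrix(B %*% Y)
    ss <- rowSums((U[, cls == 1L, drop = FALSE] -
                     rowMeans(U[, cls == 1L, drop = FALSE]))^2) +
      rowSums((U[, cls == 2L, drop = FALSE] -
                 rowMeans(U[, cls == 2L, drop = FALSE]))^2)
    s2 <- ss / (n - 2L)
    se <- sqrt(kappa * s2)
    df <- rep(n - 2, J)
  } else {
    a_j <- rowSums(as.matrix(B %*% influence$Lambda)^2)  # ||Lambda' b||^2
    c_j <- Matrix::rowSums(B^2)
    se2 <- kappa * (comp$sigma2_g * a_j + comp$sigma2_e * c_j)
    se <- sqrt(se2)
    g <- kappa * cbind(a_j, c_j)[, comp$free, drop = FALSE]
    if (any(comp$free)) {
      info <- comp$info[comp$free, comp$free, drop = FALSE]
      var_se2 <- rowSums((g %*% solve(info)) * g)
      df <- 2 * se2^2 / pmax(var_se2, .Machine$double.eps)
    } else {
      df <- rep(Inf, J)
    }
  }

  tstat <- numeric(J)
  zero_se <- se == 0
  if (any(zero_se)) {
    if (any(abs(contrast[zero_se]) > 1e-12))
      fail("singular covariance: zero contrast variance with non-zero contrast")
    warning("zero contrast variance for some pathway(s); statistic set to 0",
            call. = FALSE)
  }
  tstat[!zero_se] <- contrast[!zero_se] / se[!zero_se]
  pval <- 2 * stats::pt(-abs(tstat), df)

  out <- data.frame(pathway_id = elig, layer = "metabolite", T = tstat,
                    df = df, p_value = pval,
                    rank = rank_pathways(pval, tstat, elig),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "sigma2_g") <- comp$sigma2_g %||% NA_real_
  attr(out, "sigma2_e") <- comp$sigma2_e %||% NA_real_
  attr(out, "se_method") <- se_method
  attr(out, "ineligible") <- setdiff(pathways$ids, elig)
  out
}
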