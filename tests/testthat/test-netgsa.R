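ring_network <- function(ids) {
  build_metabolite_network(data.frame(
    reaction_id = sprintf("r%03d", seq_along(ids)),
    substrates = ids, products = ids[c(2:length(ids), 1L)],
    stringsAsFactors = FALSE))
}

test_that("influence matrix has its closed forms", {
  # rho = 0: identity, for any network
  ids <- sprintf("M%02d", 1:6)
  net <- ring_network(ids)
  infl0 <- influence_matrix(net, 0)
  expect_equal(infl0$Lambda, diag(6), ignore_attr = TRUE, tolerance = 1e-14)
  # 2 nodes, 1 edge, rho = 0.5: [[4/3, 2/3], [2/3, 4/3]]
  net2 <- build_metabolite_network(data.frame(
    reaction_id = "r1", substrates = "A", products = "B"))
  infl2 <- influence_matrix(net2, 0.5)
  expect_equal(infl2$Lambda,
               matrix(c(4, 2, 2, 4) / 3, 2, 2), ignore_attr = TRUE,
               tolerance = 1e-12)
  # isolated node keeps an identity row
  infl3 <- influence_matrix(net2, 0.5, metabolites = "Z")
  zrow <- infl3$Lambda["Z", ]
  expect_equal(unname(zrow), c(0, 0, 1), tolerance = 1e-14)
  expect_error(influence_matrix(net2, 1), "rho")
  expect_error(influence_matrix(net2, -0.1), "rho")
})

sim_metab_study <- function(seed, p = 24, n1 = 7, n2 = 5, shift = NULL) {
  set.seed(seed)
  ids <- sprintf("M%02d", seq_len(p))
  m <- named_matrix(rnorm(p * (n1 + n2)), p, n1 + n2, prefix = "M")
  rownames(m) <- ids
  lab <- two_class_labels(n1, n2)
  colnames(m) <- names(lab)
  if (!is.null(shift)) m[shift$rows, unclass(lab) == 2L] <-
      m[shift$rows, unclass(lab) == 2L] + shift$by
  pw <- pathway_set(metabolite_sets = list(
    P1 = ids[1:6], P2 = ids[7:12], P3 = ids[13:18], P4 = ids[19:24]))
  list(m = m, lab = lab, pw = pw, ids = ids)
}

test_that("the no-network limit reduces exactly to the profile t-test", {
  for (seed in 1:5) {
    s <- sim_metab_study(seed)
    infl <- influence_matrix(ring_network(s$ids), 0)
    res <- netgsa_enrich(omics_matrix(s$m, "metabolite"), s$lab, infl,
                         s$pw, sigma2_g = 0)
    for (pid in res$pathway_id) {
      mem <- s$pw$metabolite_members[[pid]]
      prof <- colMeans(s$m[mem, , drop = FALSE])
      tt <- stats::t.test(prof[unclass(s$lab) == 2L],
                          prof[unclass(s$lab) == 1L], var.equal = TRUE)
      expect_equal(res$T[res$pathway_id == pid], unname(tt$statistic),
                   tolerance = 1e-8)
      expect_equal(res$p_value[res$pathway_id == pid], tt$p.value,
                   tolerance = 1e-8)
      expect_equal(res$df[res$pathway_id == pid],
                   unname(tt$parameter))
    }
  }
})

test_that("identical class means give zero statistics", {
  s <- sim_metab_study(4, n1 = 5, n2 = 5)
  # class 2 columns are a relabelled copy of class 1
  s$m[, unclass(s$lab) == 2L] <- s$m[, unclass(s$lab) == 1L]
  infl <- influence_matrix(ring_network(s$ids), 0.3)
  res <- netgsa_enrich(omics_matrix(s$m, "metabolite"), s$lab, infl, s$pw)
  expect_true(all(abs(res$T) < 1e-12))
})

test_that("statistics are equivariant under metabolite relabelling", {
  s <- sim_metab_study(8)
  net <- ring_network(s$ids)
  infl <- influence_matrix(net, 0.4)
  res <- netgsa_enrich(omics_matrix(s$m, "metabolite"), s$lab, infl, s$pw)
  # rename every metabolite (reverse alphabetical ids), same structure
  map <- stats::setNames(sprintf("X%02d", rev(seq_along(s$ids))), s$ids)
  m2 <- s$m
  rownames(m2) <- map[rownames(m2)]
  net2 <- net
  net2$nodes <- unname(map[net$nodes])
  net2$edges$from <- unname(map[net$edges$from])
  net2$edges$to <- unname(map[net$edges$to])
  net2 <- build_metabolite_network(data.frame(
    reaction_id = sprintf("r%03d", seq_len(nrow(net2$edges))),
    substrates = net2$edges$from, products = net2$edges$to))
  pw2 <- pathway_set(metabolite_sets = lapply(
    s$pw$metabolite_members, function(x) unname(map[x])))
  infl2 <- influence_matrix(net2, 0.4)
  res2 <- netgsa_enrich(omics_matrix(m2, "metabolite"), s$lab, infl2, pw2)
  expect_equal(res2$T, res$T, tolerance = 1e-10)
})

test_that("REML recovers the generating variance components", {
  p <- 60
  ids <- sprintf("M%03d", seq_len(p))
  infl <- influence_matrix(ring_network(ids), 0.3)
  lab <- two_class_labels(16, 12)
  pw <- pathway_set(metabolite_sets = list(
    P1 = ids[1:10], P2 = ids[11:20], P3 = ids[21:30], P4 = ids[31:40]))
  for (seed in 1:5) {
    set.seed(400 + seed)
    Y <- sapply(seq_len(28), function(i)
      drop(infl$Lambda %*% rnorm(p, 0, sqrt(0.6))) + rnorm(p))
    dimnames(Y) <- list(ids, names(lab))
    res <- netgsa_enrich(omics_matrix(Y, "metabolite"), lab, infl, pw)
    expect_gte(attr(res, "sigma2_g"), 0)
    expect_gte(attr(res, "sigma2_e"), 0)
    expect_lt(abs(attr(res, "sigma2_g") - 0.6) / 0.6, 0.5)
    expect_lt(abs(attr(res, "sigma2_e") - 1) / 1, 0.5)
  }
})

test_that("the model-based SE route gives valid Satterthwaite inference", {
  s <- sim_metab_study(12, shift = list(rows = 1:6, by = 1.5))
  infl <- influence_matrix(ring_network(s$ids), 0.3)
  res <- netgsa_enrich(omics_matrix(s$m, "metabolite"), s$lab, infl, s$pw,
                       se_method = "model")
  expect_true(all(res$df > 0))
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
  expect_setequal(res$rank, seq_len(nrow(res)))
  expect_equal(res$pathway_id[res$rank == 1L], "P1")
})
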