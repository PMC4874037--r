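test_that("combined score evaluates the published equation", {
  expect_identical(combined_score(10, 2, 20, 4, J = 87), 78 / 2 + 68 / 4)
  expect_identical(combined_score(1, 1, 1, 1, J = 87), 174)
  expect_identical(combined_score(87, 1, 87, 1, J = 87), 2)
  # strictly decreasing in each mean rank and (for Rg < J + 1) in each SD
  expect_lt(combined_score(11, 2, 20, 4, J = 87),
            combined_score(10, 2, 20, 4, J = 87))
  expect_lt(combined_score(10, 3, 20, 4, J = 87),
            combined_score(10, 2, 20, 4, J = 87))
  # SD floor kicks in below s_floor
  expect_equal(combined_score(1, 0, 1, 0, J = 87, s_floor = 0.5),
               87 / 0.5 * 2)
  # the alternative parenthesization for sensitivity analysis
  expect_equal(combined_score(10, 2, 20, 4, J = 87,
                              variant = "reversed_minus_ratio"),
               (88 - 10 / 2) + (88 - 20 / 4))
  expect_error(combined_score(0, 1, 1, 1, J = 87), "mean ranks")
})

const_rank_fn <- function(ids) {
  force(ids)
  function(Y, cls, seed)
    data.frame(pathway_id = ids, rank = seq_along(ids))
}

test_that("bootstrap rank moments follow the resampled rankings", {
  st <- generate_study(calibration_config(23))
  expr <- preprocess(st$expression)
  ids <- sprintf("P%02d", 1:10)
  # deterministic enrichment: identical ranks in every resample -> S = 0
  b <- suppressMessages(bootstrap_rankings(expr, st$labels,
                                           const_rank_fn(ids),
                                           n_boot = 5, seed = 1))
  expect_true(all(b$S == 0))
  expect_equal(b$R, seq_along(ids))
  # any full permutation per resample conserves the mean rank (J + 1) / 2
  perm_fn <- function(Y, cls, seed) {
    r <- withr::with_seed(seed, sample(seq_along(ids)))
    data.frame(pathway_id = ids, rank = r)
  }
  b2 <- suppressMessages(bootstrap_rankings(expr, st$labels, perm_fn,
                                            n_boot = 200, seed = 2))
  expect_equal(mean(b2$R), (length(ids) + 1) / 2, tolerance = 1e-12)
  # bit-for-bit reproducible for a fixed seed
  b3 <- suppressMessages(bootstrap_rankings(expr, st$labels, perm_fn,
                                            n_boot = 200, seed = 2))
  expect_identical(b2, b3)
  # persistent enrichment failure aborts with the resample index
  fail_fn <- function(Y, cls, seed) stop("boom")
  expect_error(suppressMessages(
    bootstrap_rankings(expr, st$labels, fail_fn, n_boot = 2, seed = 1)),
    "10 redraws")
})

test_that("the Grubbs outlier test matches its brute-force formula", {
  # 86 near-constant background scores plus one extreme value
  set.seed(6)
  bg <- rnorm(86, 1, 0.2)
  tab <- data.frame(pathway_id = sprintf("P%02d", 1:87),
                    score = c(bg, 100))
  out <- outlier_pathways(tab, alpha = 0.05)
  expect_true(out$is_top[out$pathway_id == "P87"])
  # brute-force G and t-based p for the first iteration
  G <- (100 - mean(tab$score)) / sd(tab$score)
  N <- 87
  t2 <- N * (N - 2) * G^2 / ((N - 1)^2 - N * G^2)
  p_ref <- min(1, N * stats::pt(sqrt(t2), N - 2, lower.tail = FALSE))
  expect_equal(out$grubbs_p[out$pathway_id == "P87"], p_ref,
               tolerance = 1e-12)
  # flagged scores always exceed the mean
  expect_true(all(out$score[out$is_top] > mean(tab$score)))
  # exactly constant background: G sits at its theoretical maximum
  # (N - 1) / sqrt(N), the most extreme configuration possible, p = 0
  tab2 <- data.frame(pathway_id = tab$pathway_id,
                     score = c(rep(1, 86), 100))
  out2 <- outlier_pathways(tab2, alpha = 0.05)
  expect_equal(out2$grubbs_p[out2$pathway_id == "P87"], 0)
  expect_true(out2$is_top[out2$pathway_id == "P87"])
})

test_that("degenerate score vectors yield no outliers", {
  tab <- data.frame(pathway_id = sprintf("P%d", 1:6), score = rep(3, 6))
  expect_message(out <- outlier_pathways(tab, alpha = 0.05), "zero score SD")
  expect_false(any(out$is_top))
  expect_error(outlier_pathways(tab[1:3, ], alpha = 0.05), "at least 4")
})

test_that("concordance matches hand and brute-force evaluation", {
  mk <- function(r) data.frame(pathway_id = sprintf("P%d", seq_along(r)),
                               rank = r)
  # identical rankings: fraction 1 by the |0| <= 0 convention
  c1 <- concordance(mk(1:5), mk(1:5))
  expect_equal(c1$fraction, 1)
  expect_equal(c1$sd_of_differences, 0)
  # J = 4 hand example
  c2 <- concordance(mk(c(1, 2, 3, 4)), mk(c(2, 1, 4, 3)))
  expect_equal(c2$sd_of_differences, sqrt(4 / 3), tolerance = 1e-12)
  expect_equal(c2$fraction, 1)
  # anti-correlated ranks vs a brute-force loop
  rg <- 1:10
  rm <- 10:1
  c3 <- concordance(mk(rg), mk(rm))
  d <- rg - rm
  frac_ref <- sum(abs(d - mean(d)) <= sd(d)) / 10
  expect_equal(c3$fraction, frac_ref)
  expect_true(c3$fraction >= 0 && c3$fraction <= 1)
  # symmetric in its two arguments
  expect_equal(concordance(mk(rm), mk(rg))$fraction, c3$fraction)
  expect_error(concordance(mk(1:4), mk(1:5)), "P5")
})

test_that("combine_layers assembles the score table and nominates outliers", {
  J <- 20
  ids <- sprintf("P%02d", 1:J)
  bg <- data.frame(pathway_id = ids, R = c(1, 2:J), S = rep(2, J))
  bm <- data.frame(pathway_id = ids, R = c(1, 2:J), S = rep(2, J))
  bg$S[1] <- bm$S[1] <- 0.6  # stable winner
  tab <- combine_layers(bg, bm, alpha = 0.05)
  expect_equal(tab$pathway_id[1], "P01")
  expect_equal(tab$score[1], combined_score(1, 0.6, 1, 0.6, J = J))
  expect_true(tab$is_top[1])
  expect_error(combine_layers(bg[-1, ], bm), "P01")
})
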