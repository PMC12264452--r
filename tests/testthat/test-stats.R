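grid_adjacency <- function(n_ch) {
  # chain adjacency: channel i neighbours i-1 and i+1
  a <- matrix(FALSE, n_ch, n_ch)
  for (i in seq_len(n_ch - 1)) a[i, i + 1] <- a[i + 1, i] <- TRUE
  a
}

test_that("identical paired conditions produce no clusters", {
  set.seed(30)
  a <- array(rnorm(6 * 4 * 10), dim = c(6, 4, 10))
  ct <- cluster_permutation_test(a, a, grid_adjacency(4), paired = TRUE,
                                 n_perm = 100)
  expect_true(all(abs(ct$t) < 1e-6))
  expect_length(ct$clusters, 0)
})

test_that("an overwhelming constant offset yields one cluster at the Monte Carlo floor", {
  set.seed(31)
  a <- array(rnorm(8 * 4 * 10, sd = 0.01), dim = c(8, 4, 10))
  b <- a + 5
  ct <- cluster_permutation_test(b, a, grid_adjacency(4), paired = TRUE,
                                 n_perm = 200)
  expect_length(ct$clusters, 1)
  cl <- ct$clusters[[1]]
  expect_equal(nrow(cl$members), 4 * 10)     # every channel-time point
  # Monte Carlo floor: only sign patterns replicating the observed map tie it
  expect_lte(cl$p, 5 / 201)
  expect_true(cl$significant)
  expect_equal(cl$sign, 1)
})

test_that("clusters confined to a single electrode are discarded", {
  set.seed(32)
  a <- array(rnorm(10 * 4 * 12, sd = 1), dim = c(10, 4, 12))
  b <- a
  b[, 2, 5:7] <- b[, 2, 5:7] + 10   # strong effect on one channel only
  adj <- matrix(FALSE, 4, 4)        # no spatial neighbours at all
  adj[1, 3] <- adj[3, 1] <- adj[2, 4] <- adj[4, 2] <- TRUE
  ct <- cluster_permutation_test(b, a, adj, paired = TRUE, n_perm = 100)
  for (cl in ct$clusters) {
    expect_gte(length(unique(cl$members[, 1])), 2)
  }
  expect_false(any(vapply(ct$clusters, function(cl)
    all(cl$members[, 1] == 2), logical(1))))
})

test_that("permutation results are seed-reproducible", {
  base <- array(rnorm(6 * 4 * 8), dim = c(6, 4, 8))
  eff <- base + array(rnorm(6 * 4 * 8, 0.6), dim = c(6, 4, 8))
  run <- function() cluster_permutation_test(eff, base, grid_adjacency(4),
                                             paired = TRUE, n_perm = 150)
  set.seed(33); r1 <- run()
  set.seed(33); r2 <- run()
  expect_identical(vapply(r1$clusters, `[[`, numeric(1), "p"),
                   vapply(r2$clusters, `[[`, numeric(1), "p"))
  expect_identical(r1$tail_null, r2$tail_null)
})

test_that("independent-design t maps match stats::t.test pointwise", {
  set.seed(34)
  a <- array(rnorm(7 * 3 * 5), dim = c(7, 3, 5))
  b <- array(rnorm(9 * 3 * 5, 0.4), dim = c(9, 3, 5))
  ct <- cluster_permutation_test(a, b, grid_adjacency(3), paired = FALSE,
                                 n_perm = 100)
  for (ch in 1:3) {
    for (ti in c(1, 5)) {
      tt <- t.test(a[, ch, ti], b[, ch, ti], var.equal = TRUE)
      expect_equal(ct$t[ch, ti], unname(tt$statistic), tolerance = 1e-10)
    }
  }
})

test_that("paired-design t maps match stats::t.test pointwise", {
  set.seed(35)
  a <- array(rnorm(8 * 3 * 4), dim = c(8, 3, 4))
  b <- array(rnorm(8 * 3 * 4, 0.3), dim = c(8, 3, 4))
  ct <- cluster_permutation_test(a, b, grid_adjacency(3), paired = TRUE,
                                 n_perm = 100)
  for (ch in 1:3) {
    tt <- t.test(a[, ch, 2], b[, ch, 2], paired = TRUE)
    expect_equal(ct$t[ch, 2], unname(tt$statistic), tolerance = 1e-10)
  }
  expect_error(cluster_permutation_test(a, b[1:5, , ], grid_adjacency(3),
                                        paired = TRUE), "equal subject")
})

test_that("BH step-up matches its definition and dominates Bonferroni", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04), 0.05), rep(TRUE, 4))
  expect_equal(fdr_bh(rep(1, 5)), rep(FALSE, 5))
  expect_equal(fdr_bh(0.04, 0.05), TRUE)
  expect_identical(fdr_bh(numeric(0)), logical(0))
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  # Bonferroni rejections are a subset of BH rejections at equal level
  set.seed(36)
  for (i in 1:20) {
    p <- runif(15)^sample(1:3, 1)
    bh <- fdr_bh(p, 0.05)
    bf <- bonferroni(p, 0.05)
    expect_true(all(bh[bf]))
  }
})

test_that("the normality gate separates normal from heavy-tailed samples", {
  set.seed(37)
  normal_calls <- replicate(40, normality_gate(list(rnorm(30), rnorm(30))))
  expect_gt(mean(normal_calls == "parametric"), 0.8)
  heavy_calls <- replicate(40, normality_gate(list(rexp(30)^2)))
  expect_gt(mean(heavy_calls == "nonparametric"), 0.8)
  expect_error(normality_gate(list(rnorm(3), c(1, 2))), "at least 3")
  expect_identical(normality_gate(list(rep(1, 10))), "nonparametric")
})

test_that("Pearson correlation matches hand computation and edge cases", {
  expect_equal(pearson_corr(1:10, 2 * (1:10) + 1)$r, 1)
  expect_equal(pearson_corr(1:10, -(1:10))$r, -1)
  res <- pearson_corr(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(res$r, 0.6)
  expect_equal(res$p, cor.test(c(1, 2, 3, 4), c(2, 1, 4, 3))$p.value)
  expect_error(pearson_corr(1:3, 1:4), "equal length")
  expect_error(pearson_corr(c(1, 1, 1), 1:3), "zero variance")
  expect_error(pearson_corr(1:2, 2:3), "at least 3")
})

test_that("paired pre/post testing gates to Wilcoxon for skewed differences", {
  set.seed(38)
  pre <- rnorm(20)
  res <- paired_test(pre, pre + rnorm(20, 0.5))
  expect_identical(res$method, "paired_t")
  res2 <- paired_test(pre, pre + rexp(20)^3)
  expect_identical(res2$method, "wilcoxon_signed_rank")
  expect_error(paired_test(1:3, 1:4), "pair up")
})
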