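labelled_dist <- function(x, labels = sprintf("s%d", seq_along(x))) {
  d <- as.matrix(dist(x))
  dimnames(d) <- list(labels, labels)
  d
}

test_that("PERMANOVA pseudo-F equals the one-way ANOVA F for Euclidean 1-D data", {
  set.seed(1)
  x <- rnorm(12)
  g <- setNames(rep(c("a", "b", "c"), each = 4), sprintf("s%d", 1:12))
  d <- labelled_dist(x)
  res <- permanova(d, g, n_perm = 99, seed = 1)
  f_aov <- summary(aov(x ~ factor(g)))[[1]]$`F value`[1]
  expect_equal(res$statistic, f_aov, tolerance = 1e-8)
  # and matches the plain-double-loop reference
  expect_equal(res$statistic, bf_pseudo_F(d, unname(g)), tolerance = 1e-12)
})

test_that("PERMANOVA agrees with the vegan implementation on the statistic", {
  set.seed(2)
  pts <- matrix(rnorm(30), 10, 3)
  d <- labelled_dist(pts[, 1]); d <- as.matrix(dist(pts))
  dimnames(d) <- list(sprintf("s%d", 1:10), sprintf("s%d", 1:10))
  g <- setNames(rep(c("a", "b"), each = 5), rownames(d))
  res <- permanova(d, g, n_perm = 49, seed = 1)
  ref <- vegan::adonis2(as.dist(d) ~ g, permutations = 49)
  expect_equal(res$statistic, ref$F[1], tolerance = 1e-10)
})

test_that("PERMANOVA exhaustive-enumeration p matches Monte-Carlo within 3 SE", {
  set.seed(3)
  x <- c(rnorm(3, 0), rnorm(3, 1.5))
  d <- labelled_dist(x)
  g <- setNames(rep(c("a", "b"), each = 3), rownames(d))
  obs <- bf_pseudo_F(d, unname(g))
  splits <- combn(6, 3)
  null <- apply(splits, 2, function(idx) {
    gg <- rep("b", 6); gg[idx] <- "a"
    bf_pseudo_F(d, gg)
  })
  p_exact <- mean(null >= obs - 1e-12)
  n_perm <- 2000
  p_mc <- permanova(d, g, n_perm = n_perm, seed = 5)$p_value
  se <- sqrt(p_exact * (1 - p_exact) / n_perm)
  expect_lt(abs(p_mc - p_exact), 3 * se + 2 / n_perm)
})

test_that("PERMANOVA flags degenerate zero-within-variance input and validates groups", {
  d <- matrix(1, 4, 4); diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 0; d[3, 4] <- d[4, 3] <- 0
  dimnames(d) <- list(sprintf("s%d", 1:4), sprintf("s%d", 1:4))
  g <- setNames(c("a", "a", "b", "b"), rownames(d))
  res <- permanova(d, g, n_perm = 9, seed = 1)
  expect_equal(res$status, "degenerate")
  expect_true(is.na(res$statistic))
  expect_error(permanova(d, setNames(rep("a", 4), rownames(d))), "2 groups")
})

test_that("PERMANOVA is invariant to sample order and group renaming", {
  set.seed(4)
  x <- rnorm(10)
  d <- labelled_dist(x)
  g <- setNames(rep(c("a", "b"), 5), rownames(d))
  r1 <- permanova(d, g, n_perm = 99, seed = 2)
  perm <- sample(10)
  r2 <- permanova(d[perm, perm], g[perm], n_perm = 99, seed = 2)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-12)
  g2 <- setNames(ifelse(g == "a", "group_one", "group_two"), names(g))
  expect_equal(permanova(d, g2, n_perm = 99, seed = 2)$statistic, r1$statistic)
})

test_that("pairwise PERMANOVA applies the Bonferroni cap over group pairs", {
  set.seed(5)
  x <- rnorm(16)
  d <- labelled_dist(x)
  g2 <- setNames(rep(c("a", "b"), each = 8), rownames(d))
  pw2 <- pairwise_permanova(d, g2, n_perm = 99, seed = 1)
  expect_equal(nrow(pw2), 1L)
  expect_equal(pw2$p_adjusted, pw2$p_value)  # a = 2: adjusted equals raw
  g4 <- setNames(rep(c("a", "b", "c", "e"), each = 4), rownames(d))
  pw4 <- pairwise_permanova(d, g4, n_perm = 99, seed = 1)
  expect_equal(nrow(pw4), 6L)
  expect_equal(pw4$p_adjusted, pmin(1, pw4$p_value * 6))
})

test_that("beta-dispersion distances match vegan and direct coordinates for Euclidean input", {
  set.seed(6)
  pts <- rbind(matrix(rnorm(20, sd = 1), 10, 2), matrix(rnorm(20, sd = 3), 10, 2))
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(sprintf("s%d", 1:20), sprintf("s%d", 1:20))
  g <- setNames(rep(c("a", "b"), each = 10), rownames(d))
  res <- beta_dispersion(d, g, n_perm = 99, seed = 1)
  # coordinate oracle: distances to the group centroid in the original space
  direct <- numeric(20)
  for (k in 1:2) {
    idx <- (1:10) + (k - 1) * 10
    cen <- colMeans(pts[idx, ])
    direct[idx] <- sqrt(rowSums(sweep(pts[idx, ], 2, cen)^2))
  }
  expect_equal(unname(res$distances), direct, tolerance = 1e-8)
  ref <- vegan::betadisper(as.dist(d), g, type = "centroid")
  expect_equal(unname(res$distances), unname(ref$distances), tolerance = 1e-8)
})

test_that("beta-dispersion sees no effect between rigid copies and finds planted inflation", {
  set.seed(7)
  shape <- matrix(rnorm(16), 8, 2)
  pts <- rbind(shape, sweep(shape, 2, c(50, 50), `+`))  # rigid translated copy
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(sprintf("s%d", 1:16), sprintf("s%d", 1:16))
  g <- setNames(rep(c("a", "b"), each = 8), rownames(d))
  res <- beta_dispersion(d, g, n_perm = 199, seed = 2)
  expect_lt(res$statistic, 1e-10)
  expect_gt(res$p_value, 0.9)
  # same shape scaled x5: observed F beats its permutation null
  pts2 <- rbind(shape, sweep(shape * 5, 2, c(50, 50), `+`))
  shape20 <- matrix(rnorm(80), 40, 2)
  pts2 <- rbind(shape20[1:20, ], sweep(shape20[21:40, ] * 5, 2, c(50, 50), `+`))
  d2 <- as.matrix(dist(pts2))
  dimnames(d2) <- list(sprintf("s%d", 1:40), sprintf("s%d", 1:40))
  g2 <- setNames(rep(c("a", "b"), each = 20), rownames(d2))
  res2 <- beta_dispersion(d2, g2, n_perm = 199, seed = 3)
  expect_lt(res2$p_value, 0.05)
  expect_error(beta_dispersion(d2[1:21, 1:21], g2[1:21], 9, 1), "size 1")
})

test_that("indicator statistics follow the group-size-equalized formula", {
  pres <- rbind(s1 = c(f1 = 1, f2 = 1, f3 = 0),
                s2 = c(f1 = 1, f2 = 1, f3 = 0),
                s3 = c(f1 = 0, f2 = 1, f3 = 0),
                s4 = c(f1 = 0, f2 = 1, f3 = 0))
  g <- setNames(c("pro", "pro", "syn", "syn"), rownames(pres))
  res <- indicator_species(pres, g, n_perm = 99, seed = 1)
  f1 <- res[res$feature_id == "f1", ]
  expect_equal(f1$A, 1)   # only in group pro
  expect_equal(f1$B, 1)   # in all pro samples
  expect_equal(f1$statistic, 1)
  expect_equal(f1$group, "pro")
  f2 <- res[res$feature_id == "f2", ]
  expect_equal(f2$A, 0.5) # everywhere in both equal groups
  expect_equal(f2$statistic, sqrt(0.5))
  f3 <- res[res$feature_id == "f3", ]
  expect_true(is.na(f3$statistic))  # absent everywhere: missing
  # adjusted p uses Bonferroni across features by default
  expect_equal(res$p_adjusted,
               p.adjust(res$p_value, "bonferroni"))
})

test_that("indicator permutation p matches exhaustive enumeration over 20 splits", {
  pres <- cbind(f = c(1, 1, 1, 0, 0, 1))
  rownames(pres) <- sprintf("s%d", 1:6)
  g <- setNames(rep(c("a", "b"), each = 3), rownames(pres))
  obs <- bf_indval_stat(pres[, 1], unname(g))
  splits <- combn(6, 3)
  null <- apply(splits, 2, function(idx) {
    gg <- rep("b", 6); gg[idx] <- "a"
    bf_indval_stat(pres[, 1], gg)
  })
  p_exact <- mean(null >= obs - 1e-12)
  res <- indicator_species(pres, g, n_perm = 4000, seed = 2)
  se <- sqrt(p_exact * (1 - p_exact) / 4000)
  expect_lt(abs(res$p_value - p_exact), 3 * se + 2 / 4000)
})

test_that("indicator statistic is invariant to within-group sample duplication", {
  set.seed(8)
  pres <- matrix(runif(60) < 0.4, 12, 5,
                 dimnames = list(sprintf("s%d", 1:12), sprintf("f%d", 1:5)))
  pres[, 1] <- TRUE
  g <- setNames(rep(c("a", "b"), c(4, 8)), rownames(pres))
  r1 <- indicator_species(pres, g, n_perm = 9, seed = 1)
  dup <- rbind(pres, pres)
  rownames(dup) <- sprintf("s%d", 1:24)
  gdup <- setNames(rep(unname(g), 2), rownames(dup))
  r2 <- indicator_species(dup, gdup, n_perm = 9, seed = 1)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-12)
  expect_equal(r1$A, r2$A)
  expect_equal(r1$B, r2$B)
})

test_that("Fisher exact matches enumeration and the expected invariances", {
  expect_equal(fisher_exact_2x2(matrix(c(1, 0, 0, 1), 2, 2))$p_value, 1.0)
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2, 2))$p_value,
               2 / choose(10, 5), tolerance = 1e-12)
  set.seed(9)
  for (trial in 1:50) {
    tab <- matrix(rpois(4, 6), 2, 2)
    if (sum(tab) == 0) next
    mine <- fisher_exact_2x2(tab)
    expect_equal(mine$p_value, bf_fisher_p(tab), tolerance = 1e-10)
    expect_equal(mine$p_value, fisher.test(tab)$p.value, tolerance = 1e-7)
    # transposition and simultaneous row/column swap invariance
    expect_equal(fisher_exact_2x2(t(tab))$p_value, mine$p_value, tolerance = 1e-12)
    swapped <- tab[2:1, 2:1]
    expect_equal(fisher_exact_2x2(swapped)$p_value, mine$p_value, tolerance = 1e-12)
  }
  or <- fisher_exact_2x2(matrix(c(3, 0, 1, 5), 2, 2))
  expect_equal(or$odds_ratio_status, "infinite")
})

test_that("Spearman handles monotone, tied, and small-sample exact cases", {
  expect_equal(spearman_cor(1:10, (1:10)^2)$rho, 1)
  expect_equal(spearman_cor(1:10, -(1:10))$rho, -1)
  x <- c(1, 2, 2, 3, 5, 5, 5, 8, 9, 10, 12, 1)
  y <- c(2, 1, 4, 4, 4, 7, 6, 9, 9, 11, 13, 2)
  s <- spearman_cor(x, y)
  expect_equal(s$rho, cor(rank(x), rank(y)), tolerance = 1e-12)  # mid-rank Pearson
  ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(s$rho, unname(ref$estimate), tolerance = 1e-12)
  # exact enumeration for n <= 9 agrees with cor.test's exact p when tie-free
  xs <- c(3, 1, 4, 1.5, 5, 9, 2.6)
  ys <- c(2, 7, 1.8, 2.8, 5.7, 3, 6)
  se <- spearman_cor(xs, ys)
  refe <- cor.test(xs, ys, method = "spearman")
  expect_equal(se$p_value, refe$p.value, tolerance = 1e-12)
  expect_equal(spearman_cor(1:5, rep(1, 5))$status, "constant")
  expect_error(spearman_cor(1:2, 2:1), "3 complete")
})

test_that("Goodman-Kruskal tau measures asymmetric nesting", {
  clade <- rep(c("LLI", "LLII", "LLIV", "HLI"), each = 3)
  ecotype <- rep(c("LL", "LL", "LL", "HL"), each = 3)
  expect_equal(goodman_kruskal_tau(clade, ecotype), 1)  # clade determines ecotype
  expect_lt(goodman_kruskal_tau(ecotype, clade), 1)
  expect_gt(goodman_kruskal_tau(ecotype, clade), 0)
  # independent with identical margins in a balanced 2x2
  x <- rep(c("u", "v"), 10)
  y <- rep(c("p", "p", "q", "q"), 5)
  expect_equal(goodman_kruskal_tau(x, y), 0)
  # 3x2 toy against the hand-computed value 28/70
  xs <- rep(c("r1", "r2", "r3"), each = 4)
  ys <- c("c1", "c1", "c1", "c2", "c1", "c1", "c2", "c2", "c2", "c2", "c2", "c2")
  expect_equal(goodman_kruskal_tau(xs, ys), 0.4, tolerance = 1e-12)
  expect_true(is.na(goodman_kruskal_tau(x, rep("p", 20))))
})

test_that("permutation p-values stay within their attainable range and reproduce", {
  set.seed(10)
  x <- rnorm(12)
  d <- labelled_dist(x)
  g <- setNames(rep(c("a", "b"), 6), rownames(d))
  for (np in c(19, 99)) {
    p <- permanova(d, g, n_perm = np, seed = 3)$p_value
    expect_gte(p, 1 / (np + 1))
    expect_lte(p, 1)
    expect_equal(p, permanova(d, g, n_perm = np, seed = 3)$p_value)
  }
})
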