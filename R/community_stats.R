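align_grouping <- function(d, grouping) {
  labels <- rownames(d)
  if (is.null(names(grouping))) {
    if (length(grouping) != nrow(d))
      abort_fmt("grouping length does not match the distance matrix")
    g <- as.character(grouping)
  } else {
    missing <- setdiff(labels, names(grouping))
    if (length(missing))
      abort_fmt("samples without a group label: %s", paste(missing, collapse = ", "))
    g <- as.character(grouping[labels])
  }
  factor(g)
}

permanova_F <- function(d2, gi, a, N) {
  ss_total <- sum(d2) / (2 * N)
  ss_within <- 0
  for (k in seq_len(a)) {
    idx <- which(gi == k)
    ss_within <- ss_within + sum(d2[idx, idx]) / (2 * length(idx))
  }
  ss_between <- ss_total - ss_within
  if (ss_within <= 0) return(c(NA_real_, ss_total, ss_within, ss_between))
  FF <- (ss_between / (a - 1)) / (ss_within / (N - a))
  c(FF, ss_total, ss_within, ss_between)
}

#' Permutational multivariate analysis of variance (one factor)
#'
#' Partitions the sum of squared inter-point distances into between- and
#' within-group components and tests the pseudo-F statistic by random
#' permutation of group labels, with the `(1 + x) / (1 + n)` p-value
#' convention. For Euclidean distances this pseudo-F reduces to the classical
#' one-way ANOVA F.
#'
#' @param d symmetric distance matrix with sample labels.
#' @param grouping named vector of group labels (or unnamed, in matrix order).
#' @param n_perm number of label permutations (default 1000).
#' @param seed integer seed.
#' @return list: `statistic` (pseudo-F), `ss_total`, `ss_within`,
#'   `ss_between`, `df`, `p_value`, `n_perm`, `seed`, `status` (`"ok"` or
#'   `"degenerate"` when the within-group sum of squares is zero).
#' @export
permanova <- function(d, grouping, n_perm = 1000L, seed = 1L) {
  d <- as.matrix(d)
  g <- align_grouping(d, grouping)
  a <- nlevels(g)
  N <- nrow(d)
  if (a < 2L) abort_fmt("need at least 2 groups")
  if (N < a + 1L) abort_fmt("need at least one more sample than groups")
  d2 <- d^2
  gi <- as.integer(g)
  obs <- permanova_F(d2, gi, a, N)
  if (is.na(obs[1L])) {
    return(list(statistic = NA_real_, ss_total = obs[2L], ss_within = obs[3L],
                ss_between = obs[4L], df = c(a - 1L, N - a), p_value = NA_real_,
                n_perm = n_perm, seed = seed, status = "degenerate"))
  }
  null <- with_seed(seed, vapply(seq_len(n_perm), function(p)
    permanova_F(d2, sample(gi), a, N)[1L], 0))
  list(statistic = obs[1L], ss_total = obs[2L], ss_within = obs[3L],
       ss_between = obs[4L], df = c(a - 1L, N - a),
       p_value = perm_pvalue(null, obs[1L]),
       n_perm = as.integer(n_perm), seed = seed, status = "ok")
}

#' Pairwise PERMANOVA post-hoc tests
#'
#' Runs [permanova()] on every pair of groups and adjusts the p-values for
#' the number of pairs (Bonferroni by default).
#'
#' @inheritParams permanova
#' @param correction a [stats::p.adjust] method; default `"bonferroni"`.
#' @return data.frame: group1, group2, statistic, p_value, p_adjusted.
#' @export
pairwise_permanova <- function(d, grouping, n_perm = 1000L, seed = 1L,
                               correction = "bonferroni") {
  d <- as.matrix(d)
  g <- align_grouping(d, grouping)
  pairs <- combn(levels(g), 2L)
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    keep <- g %in% pairs[, k]
    sub <- permanova(d[keep, keep, drop = FALSE], droplevels(g[keep]),
                     n_perm = n_perm, seed = seed + k)
    data.frame(group1 = pairs[1L, k], group2 = pairs[2L, k],
               statistic = sub$statistic, p_value = sub$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- p.adjust(out$p_value, method = correction)
  out
}

centroid_distances <- function(coords, coords_neg, gi, a) {
  z2 <- numeric(length(gi))
  for (k in seq_len(a)) {
    idx <- which(gi == k)
    cp <- colMeans(coords[idx, , drop = FALSE])
    dp2 <- rowSums(sweep(coords[idx, , drop = FALSE], 2L, cp)^2)
    dn2 <- 0
    if (ncol(coords_neg)) {
      cn <- colMeans(coords_neg[idx, , drop = FALSE])
      dn2 <- rowSums(sweep(coords_neg[idx, , drop = FALSE], 2L, cn)^2)
    }
    z2[idx] <- dp2 - dn2
  }
  sqrt(pmax(0, z2))
}

anova_F <- function(z, gi, a) {
  N <- length(z)
  gm <- mean(z)
  ssb <- 0; ssw <- 0
  for (k in seq_len(a)) {
    zk <- z[gi == k]
    ssb <- ssb + length(zk) * (mean(zk) - gm)^2
    ssw <- ssw + sum((zk - mean(zk))^2)
  }
  if (ssw <= 0) return(NA_real_)
  (ssb / (a - 1)) / (ssw / (N - a))
}

#' Multivariate homogeneity of group dispersions
#'
#' Embeds the distance matrix by principal coordinates, computes each
#' sample's distance to its group centroid (corrected for negative-eigenvalue
#' axes as `sqrt(max(0, d+^2 - d-^2))`), and tests the one-way ANOVA F on
#' these distances by permutation of group labels with full recomputation of
#' centroids and distances per permutation.
#'
#' @inheritParams permanova
#' @return list: `distances` (per-sample distance to group centroid),
#'   `statistic` (F), `p_value`, `n_perm`, `seed`.
#' @export
beta_dispersion <- function(d, grouping, n_perm = 999L, seed = 1L) {
  d <- as.matrix(d)
  g <- align_grouping(d, grouping)
  a <- nlevels(g)
  if (a < 2L) abort_fmt("need at least 2 groups")
  sizes <- table(g)
  if (any(sizes < 2L))
    abort_fmt("group of size 1: %s", paste(names(sizes)[sizes < 2L], collapse = ", "))
  pc <- pcoa(d)
  gi <- as.integer(g)
  z <- centroid_distances(pc$coordinates, pc$coordinates_neg, gi, a)
  obs <- anova_F(z, gi, a)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(p) {
    gp <- sample(gi)
    anova_F(centroid_distances(pc$coordinates, pc$coordinates_neg, gp, a), gp, a)
  }, 0))
  list(distances = setNames(z, rownames(d)), statistic = obs,
       p_value = perm_pvalue(null[!is.na(null)], obs),
       n_perm = as.integer(n_perm), seed = seed)
}

#' Pairwise beta-dispersion post-hoc tests
#'
#' Runs [beta_dispersion()] on every pair of groups and adjusts p-values for
#' the number of pairs.
#'
#' @inheritParams pairwise_permanova
#' @return data.frame: group1, group2, statistic, p_value, p_adjusted.
#' @export
pairwise_beta_dispersion <- function(d, grouping, n_perm = 999L, seed = 1L,
                                     correction = "bonferroni") {
  d <- as.matrix(d)
  g <- align_grouping(d, grouping)
  pairs <- combn(levels(g), 2L)
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    keep <- g %in% pairs[, k]
    sub <- beta_dispersion(d[keep, keep, drop = FALSE], droplevels(g[keep]),
                           n_perm = n_perm, seed = seed + k)
    data.frame(group1 = pairs[1L, k], group2 = pairs[2L, k],
               statistic = sub$statistic, p_value = sub$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- p.adjust(out$p_value, method = correction)
  out
}

indval_stats <- function(inc, sizes) {
  # inc: features x groups incidence counts; returns A, B, stat, best group
  relfreq <- sweep(inc, 2L, sizes, `/`)       # B per group
  denom <- rowSums(relfreq)
  A <- relfreq / ifelse(denom > 0, denom, 1)  # group-size-equalized specificity
  stat <- sqrt(A * relfreq)
  best <- max.col(stat, ties.method = "first")
  list(A = A, B = relfreq, stat = stat, best = best,
       best_stat = stat[cbind(seq_len(nrow(stat)), best)])
}

#' Indicator species analysis on presence/absence
#'
#' For each feature and group, specificity `A` is the group's incidence rate
#' relative to all groups' rates (group-size equalized) and fidelity `B` is
#' the within-group incidence rate; the indicator statistic is
#' `sqrt(A * B)` maximized over groups, tested by permutation of sample
#' labels with the `(1 + x) / (1 + n)` convention and adjusted across
#' features.
#'
#' @param presence logical or numeric matrix, samples x features (presence is
#'   value > 0).
#' @param grouping named vector of group labels per sample.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param p_adjust a [stats::p.adjust] method applied across features;
#'   default `"bonferroni"`.
#' @return data.frame per feature: feature_id, group (best), A, B,
#'   statistic, p_value, p_adjusted; features absent everywhere carry `NA`.
#' @export
indicator_species <- function(presence, grouping, n_perm = 999L, seed = 1L,
                              p_adjust = "bonferroni") {
  pres <- (as.matrix(presence) > 0) * 1
  g <- align_grouping(pres, grouping)
  if (nlevels(g) < 2L) abort_fmt("need at least 2 groups")
  sizes <- as.numeric(table(g))
  G <- stats::model.matrix(~ g - 1)            # samples x groups indicator
  inc <- t(pres) %*% G                         # features x groups incidence
  obs <- indval_stats(inc, sizes)
  absent <- colSums(pres) == 0
  null_count <- with_seed(seed, {
    cnt <- numeric(ncol(pres))
    for (p in seq_len(n_perm)) {
      Gp <- G[sample(nrow(G)), , drop = FALSE]
      st <- indval_stats(t(pres) %*% Gp, sizes)$best_stat
      cnt <- cnt + (st >= obs$best_stat - 1e-12)
    }
    cnt
  })
  p <- (1 + null_count) / (1 + n_perm)
  out <- data.frame(
    feature_id = colnames(pres),
    group = levels(g)[obs$best],
    A = obs$A[cbind(seq_len(ncol(pres)), obs$best)],
    B = obs$B[cbind(seq_len(ncol(pres)), obs$best)],
    statistic = obs$best_stat,
    p_value = p, stringsAsFactors = FALSE)
  out[absent, c("group")] <- NA
  out[absent, c("A", "B", "statistic", "p_value")] <- NA_real_
  out$p_adjusted <- p.adjust(out$p_value, method = p_adjust)
  rownames(out) <- NULL
  out
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' The two-sided p-value sums the hypergeometric probabilities of every table
#' with the observed margins whose probability does not exceed the observed
#' table's (within a 1e-7 relative slack); the odds ratio is the sample
#' `(a*d)/(b*c)`, with infinite and undefined cases flagged.
#'
#' @param tab 2x2 matrix of non-negative integers.
#' @return list: `p_value`, `odds_ratio`, `odds_ratio_status` (`"finite"`,
#'   `"infinite"`, `"undefined"`).
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2L) || any(tab < 0) || any(tab != round(tab)))
    abort_fmt("need a 2x2 table of non-negative integers")
  a <- tab[1L, 1L]; b <- tab[1L, 2L]; c_ <- tab[2L, 1L]; d <- tab[2L, 2L]
  if (sum(tab) == 0) abort_fmt("need at least one positive margin")
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_
  x <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(x, r1, r2, c1)
  dobs <- dhyper(a, r1, r2, c1)
  p <- min(1, sum(probs[probs <= dobs * (1 + 1e-7)]))
  or <- if (b == 0 && c_ == 0 && (a == 0 || d == 0)) {
    NA_real_
  } else if (b * c_ == 0) {
    if (a * d == 0) NA_real_ else Inf
  } else a * d / (b * c_)
  status <- if (is.na(or)) "undefined" else if (is.infinite(or)) "infinite" else "finite"
  list(p_value = p, odds_ratio = or, odds_ratio_status = status)
}

#' Spearman rank correlation with a tie-corrected estimate
#'
#' Pearson correlation on mid-ranks; two-sided p via the t approximation with
#' n-2 degrees of freedom for n > 9, and by exact enumeration of all n!
#' pairings for n <= 9.
#'
#' @param x,y paired numeric vectors (pairs with missing values are dropped).
#' @return list: `rho`, `p_value`, `n`, `status` (`"ok"` or `"constant"` when
#'   either variable has no variation).
#' @export
spearman_cor <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) abort_fmt("need at least 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n = n, status = "constant"))
  rho <- cor(rx, ry)
  if (n > 9L) {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tt), n - 2)
  } else {
    perms <- all_permutations(n)
    mx <- rx - mean(rx); my <- ry - mean(ry)
    denom <- sqrt(sum(mx^2) * sum(my^2))
    rho_null <- (matrix(my[perms], nrow(perms)) %*% mx) / denom
    p <- mean(abs(rho_null) >= abs(rho) - 1e-12)
  }
  list(rho = rho, p_value = min(1, p), n = n, status = "ok")
}

#' Goodman-Kruskal tau
#'
#' The proportional reduction in Gini variation of `y` given `x`:
#' `tau(x -> y) = (sum_ij n_ij^2 / n_i. - sum_j n_.j^2 / n) /
#'                (n - sum_j n_.j^2 / n)`.
#' Asymmetric in its arguments; 1 when `y` is a deterministic function of `x`.
#'
#' @param x,y paired categorical vectors (pairs with missing values dropped).
#' @return tau in \[0,1\], or `NA` when `y` is constant.
#' @export
goodman_kruskal_tau <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  tab <- table(x[keep], y[keep])
  n <- sum(tab)
  if (n == 0) abort_fmt("no complete pairs")
  vy <- n - sum(colSums(tab)^2) / n
  if (vy == 0) return(NA_real_)
  vyx <- sum(tab^2 / rowSums(tab)) - sum(colSums(tab)^2) / n
  vyx / vy
}
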