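#' Per-sample richness above a relative-abundance threshold
#'
#' @param rel relative-abundance matrix (host-excluded), samples x features.
#' @param threshold minimum relative abundance; features at or above it are
#'   counted (default 0.002).
#' @return named integer vector of per-sample feature counts.
#' @export
richness_at_threshold <- function(rel, threshold = 0.002) {
  rowSums(rel >= threshold & rel > 0)
}

#' Rarefaction richness
#'
#' Mean number of distinct features observed across repeated uniform
#' without-replacement subsamples of a fixed depth.
#'
#' @param counts count matrix, samples x features.
#' @param depth subsample size; defaults to the minimum per-sample total.
#' @param reps number of subsamples per sample.
#' @param seed integer seed.
#' @return named numeric vector; samples whose total is below `depth` are
#'   emitted as `NA` with a warning.
#' @export
rarefaction_richness <- function(counts, depth = NULL, reps = 100L, seed = 1L) {
  validate_count_table(counts)
  if (reps < 1L) abort_fmt("reps must be >= 1")
  tot <- rowSums(counts)
  if (is.null(depth)) depth <- min(tot)
  out <- setNames(rep(NA_real_, nrow(counts)), rownames(counts))
  shallow <- tot < depth
  if (any(shallow))
    warning(sprintf("samples below rarefaction depth emitted as NA: %s",
                    paste(rownames(counts)[shallow], collapse = ", ")))
  with_seed(seed, {
    for (i in which(!shallow)) {
      x <- counts[i, ]
      cs <- cumsum(x)
      out[i] <- mean(vapply(seq_len(reps), function(r) {
        pos <- sample.int(tot[i], depth)
        length(unique(findInterval(pos - 0.5, c(0, cs))))
      }, 0))
    }
  })
  out
}

#' Closed-form expected rarefaction richness
#'
#' The hypergeometric expectation
#' `E[S] = sum_i (1 - choose(N - N_i, d) / choose(N, d))`.
#'
#' @param x integer vector of feature counts for one sample.
#' @param depth subsample size.
#' @return expected number of distinct features.
#' @export
expected_rarefaction_richness <- function(x, depth) {
  x <- x[x > 0]
  N <- sum(x)
  if (depth > N) abort_fmt("depth exceeds the sample total")
  sum(1 - exp(lchoose(N - x, depth) - lchoose(N, depth)))
}

#' Unweighted UniFrac distances
#'
#' For each pair of samples, the branch length leading exclusively to tips
#' present in one sample only, over the branch length leading to tips
#' present in either: a branch counts when any tip of its subtree is in the
#' relevant set. Abundances are ignored (presence is value > 0). Any root
#' edge above the deepest split is excluded: it subtends every tip and can
#' never be unique.
#'
#' @param tree rooted [ape::phylo] tree whose tips cover all present features.
#' @param presence logical or numeric matrix, samples x features; a feature
#'   is present where the value is > 0.
#' @return symmetric distance matrix with zero diagonal; a pair of two empty
#'   samples is `NA`.
#' @export
unweighted_unifrac <- function(tree, presence) {
  pres <- presence > 0
  feats <- colnames(pres)
  missing <- setdiff(feats[colSums(pres) > 0], tree$tip.label)
  if (length(missing))
    abort_fmt("features absent from the tree: %s", paste(missing, collapse = ", "))
  n <- nrow(pres)
  samples <- rownames(pres)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  # node x sample presence, accumulated tips-up in postorder
  node_pres <- matrix(FALSE, nnode, n)
  idx <- match(tree$tip.label, feats)
  has <- !is.na(idx)
  node_pres[which(has), ] <- t(pres[, idx[has], drop = FALSE])
  tr <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    node_pres[p, ] <- node_pres[p, ] | node_pres[ch, ]
  }
  # each edge's presence per sample = its child node's subtree presence
  B <- node_pres[tr$edge[, 2L], , drop = FALSE]
  w <- tr$edge.length
  shared <- t(B) %*% (w * B)                  # sum of branch lengths in both
  si <- diag(shared)                          # branch length present per sample
  total <- outer(si, si, "+") - shared
  uniq <- total - shared
  d <- ifelse(total > 0, uniq / total, NA_real_)
  diag(d) <- 0
  dimnames(d) <- list(samples, samples)
  d
}

#' Principal coordinates analysis with explicit negative-eigenvalue axes
#'
#' Gower double-centering of `-d^2 / 2` followed by eigendecomposition;
#' coordinates are returned separately for positive- and negative-eigenvalue
#' axes so that squared distances are recoverable as (positive-block squared
#' differences) minus (negative-block squared differences).
#'
#' @param d symmetric distance matrix with zero diagonal.
#' @param tol eigenvalues within `tol * max(abs(eigenvalue))` of zero are
#'   dropped.
#' @return list of class `phyco_pcoa`: `eigenvalues` (descending),
#'   `coordinates` (positive axes), `coordinates_neg` (negative axes).
#' @export
pcoa <- function(d, tol = 1e-9) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) abort_fmt("distance matrix must be symmetric")
  n <- nrow(d)
  A <- -0.5 * d^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  lam <- eig$values
  keep <- abs(lam) > tol * max(abs(lam), 1e-300)
  lam <- lam[keep]
  vec <- eig$vectors[, keep, drop = FALSE]
  pos <- lam > 0
  coords <- sweep(vec[, pos, drop = FALSE], 2L, sqrt(lam[pos]), `*`)
  coords_neg <- sweep(vec[, !pos, drop = FALSE], 2L, sqrt(-lam[!pos]), `*`)
  rownames(coords) <- rownames(coords_neg) <- rownames(d)
  structure(list(eigenvalues = lam, coordinates = coords,
                 coordinates_neg = coords_neg),
            class = "phyco_pcoa")
}

#' Ward hierarchical clustering by Lance-Williams updates
#'
#' Agglomerative merges minimizing the Ward criterion, run on squared
#' distances with merge heights reported on the distance scale; ties are
#' broken by the lexicographically smallest pair of cluster indices, so the
#' result is deterministic.
#'
#' @param d symmetric distance matrix with labels.
#' @return an object of class `hclust` (merge, height, order, labels).
#' @export
ward_clustering <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2L) abort_fmt("need at least 2 samples")
  labels <- rownames(d) %||% as.character(seq_len(n))
  D2 <- d^2
  size <- rep(1L, n)
  active <- seq_len(n)
  id <- -seq_len(n)  # hclust convention: negative = singleton
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    best <- c(NA_integer_, NA_integer_); best_val <- Inf
    for (ai in seq_along(active)[-length(active)]) {
      for (bi in (ai + 1L):length(active)) {
        v <- D2[active[ai], active[bi]]
        if (v < best_val - 1e-12) { best_val <- v; best <- c(ai, bi) }
      }
    }
    i <- active[best[1L]]; j <- active[best[2L]]
    merge[step, ] <- sort(c(id[i], id[j]))
    height[step] <- sqrt(best_val)
    ni <- size[i]; nj <- size[j]
    for (k in active[!active %in% c(i, j)]) {
      nk <- size[k]
      D2[i, k] <- D2[k, i] <-
        ((ni + nk) * D2[i, k] + (nj + nk) * D2[j, k] - nk * best_val) /
        (ni + nj + nk)
    }
    size[i] <- ni + nj
    id[i] <- step
    active <- active[-best[2L]]
  }
  ord <- dendro_order(merge)
  structure(list(merge = merge, height = height, order = ord,
                 labels = labels, method = "ward",
                 call = match.call(), dist.method = "user"),
            class = "hclust")
}

# leaf order for plotting an hclust merge matrix
dendro_order <- function(merge) {
  expand <- function(k) {
    if (k < 0) return(-k)
    c(expand(merge[k, 1L]), expand(merge[k, 2L]))
  }
  expand(nrow(merge))
}
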