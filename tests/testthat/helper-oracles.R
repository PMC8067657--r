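# Independent reference implementations used as oracles. These deliberately
# share no code with the package: plain double loops and textbook formulas.

# brute-force adjacency filter: explicit loop over wells, features, neighbours
bf_adjacency_filter <- function(rel, layout, ratio = 0.1, scheme = "edge8") {
  out <- rel
  row_of <- setNames(layout$row, layout$sample_id)
  col_of <- setNames(layout$col, layout$sample_id)
  on_plate <- intersect(rownames(rel), layout$sample_id)
  nbrs <- lapply(on_plate, function(s) {
    hits <- character(0)
    for (s2 in on_plate) {
      if (s2 == s) next
      dr <- abs(row_of[[s2]] - row_of[[s]])
      dc <- abs(col_of[[s2]] - col_of[[s]])
      adj <- if (scheme == "edge8") dr <= 1 && dc <= 1 else dr + dc == 1
      if (adj) hits <- c(hits, s2)
    }
    hits
  })
  names(nbrs) <- on_plate
  for (s in on_plate) {
    for (f in colnames(rel)) {
      v <- rel[s, f]
      if (v <= 0) next
      mx <- 0
      for (s2 in nbrs[[s]]) if (rel[s2, f] > mx) mx <- rel[s2, f]
      if (v < ratio * mx) out[s, f] <- 0
    }
  }
  out
}

# random relative-abundance plate for filter fuzzing: sparse, with a spread of
# magnitudes so both filter rules fire
random_rel_plate <- function(n_samples = 96, n_features = 50) {
  wells <- paste0(rep(LETTERS[1:8], each = 12), rep(1:12, 8))[seq_len(n_samples)]
  samples <- sprintf("s%02d", seq_len(n_samples))
  m <- matrix(0, n_samples, n_features,
              dimnames = list(samples, sprintf("f%02d", seq_len(n_features))))
  for (i in seq_len(n_samples)) {
    k <- sample(3:12, 1)
    idx <- sample(n_features, k)
    w <- 10^runif(k, -4, 0)
    m[i, idx] <- w / sum(w)
  }
  list(rel = m, layout = plate_layout(samples, wells))
}

# branch-enumeration UniFrac for one sample pair, descendants via phangorn
bf_unifrac_pair <- function(tree, set1, set2) {
  ntip <- length(tree$tip.label)
  uniq <- 0; total <- 0
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    tips <- if (child <= ntip) tree$tip.label[child] else
      tree$tip.label[unlist(phangorn::Descendants(tree, child, "tips"))]
    in1 <- any(tips %in% set1)
    in2 <- any(tips %in% set2)
    if (in1 || in2) total <- total + tree$edge.length[e]
    if (xor(in1, in2)) uniq <- uniq + tree$edge.length[e]
  }
  if (total == 0) return(NA_real_)
  uniq / total
}

# exact two-sided Fisher p by direct enumeration with lchoose
bf_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; n <- sum(tab)
  lp <- function(x) lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1)
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- exp(vapply(xs, lp, 0))
  pobs <- exp(lp(a))
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# textbook PERMANOVA pseudo-F from a distance matrix, plain double loops
bf_pseudo_F <- function(d, groups) {
  n <- nrow(d)
  a <- length(unique(groups))
  sst <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) sst <- sst + d[i, j]^2
  sst <- sst / n
  ssw <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    s <- 0
    if (length(idx) > 1)
      for (ii in 1:(length(idx) - 1)) for (jj in (ii + 1):length(idx))
        s <- s + d[idx[ii], idx[jj]]^2
    ssw <- ssw + s / length(idx)
  }
  ((sst - ssw) / (a - 1)) / (ssw / (n - a))
}

# indicator statistic for one presence vector, direct formula
bf_indval_stat <- function(pres, groups) {
  levs <- unique(groups)
  rate <- vapply(levs, function(g) mean(pres[groups == g]), 0)
  if (sum(rate) == 0) return(NA_real_)
  max(sqrt(rate / sum(rate) * rate))
}

# random rooted tree + presence matrix instances for UniFrac properties
random_unifrac_instance <- function(n_tips = 8, n_samples = 4) {
  tree <- ape::rcoal(n_tips, tip.label = sprintf("t%02d", seq_len(n_tips)))
  pres <- matrix(runif(n_samples * n_tips) < 0.5, n_samples, n_tips,
                 dimnames = list(sprintf("s%d", seq_len(n_samples)),
                                 tree$tip.label))
  # guarantee non-empty samples so all pairwise distances are defined
  for (i in seq_len(n_samples))
    if (!any(pres[i, ])) pres[i, sample(n_tips, 1)] <- TRUE
  list(tree = tree, pres = pres)
}

# random mutated sequence families for clustering tests
random_seq_family <- function(n_centroids = 4, members_each = 4, len = 150,
                              mut_range = 1:3) {
  bases <- c("A", "C", "G", "T")
  seqs <- character(0)
  for (k in seq_len(n_centroids)) {
    centre <- sample(bases, len, replace = TRUE)
    seqs[sprintf("c%d_m0", k)] <- paste(centre, collapse = "")
    for (m in seq_len(members_each)) {
      s <- centre
      nm <- sample(mut_range, 1)
      pos <- sample(len, nm)
      for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1)
      seqs[sprintf("c%d_m%d", k, m)] <- paste(s, collapse = "")
    }
  }
  seqs
}
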