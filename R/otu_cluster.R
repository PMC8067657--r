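#' Trim primer bases from the start of each sequence
#'
#' @param seqs named character vector of nucleotide sequences.
#' @param n_bases number of leading bases to remove.
#' @return named character vector; sequences shorter than `n_bases` are
#'   dropped with a warning.
#' @export
trim_primers <- function(seqs, n_bases = 20L) {
  if (n_bases < 0) abort_fmt("n_bases must be >= 0")
  out <- substring(seqs, n_bases + 1L)
  empty <- !nzchar(out)
  if (any(empty)) {
    warning(sprintf("dropped %d sequence(s) shorter than the primer length: %s",
                    sum(empty), paste(names(seqs)[empty], collapse = ", ")))
    out <- out[!empty]
  }
  out
}

#' Truncate all sequences to the shortest length present
#'
#' @param seqs named character vector of sequences.
#' @return named character vector, all of equal length.
#' @export
trim_to_common_length <- function(seqs) {
  if (!length(seqs)) abort_fmt("empty sequence set")
  substring(seqs, 1L, min(nchar(seqs)))
}

#' Dereplicate identical sequences
#'
#' One record per distinct sequence string; abundances are summed and the
#' representative id is the lexicographically smallest member id.
#'
#' @param seqs named character vector of sequences.
#' @param abundance named numeric abundances (default 1 per sequence).
#' @return list: `seqs` (named by representative id), `abundance`, and
#'   `members` (list of member ids per representative).
#' @export
dereplicate <- function(seqs, abundance = NULL) {
  if (is.null(abundance)) abundance <- setNames(rep(1, length(seqs)), names(seqs))
  groups <- split(names(seqs), unname(seqs))
  reps <- vapply(groups, function(ids) sort(ids)[1L], "")
  out_seqs <- setNames(names(groups), reps)
  ab <- vapply(groups, function(ids) sum(abundance[ids]), 0)
  ord <- order(reps)
  list(seqs = out_seqs[ord],
       abundance = setNames(unname(ab)[ord], reps[ord]),
       members = setNames(groups[ord], reps[ord]))
}

#' Pairwise percent identity by global alignment
#'
#' Needleman-Wunsch global alignment under the configured scoring (default
#' match +5, mismatch -4, gap open -10, gap extend -1); identity is matching
#' columns over alignment columns. Under the default definition, columns
#' lying in terminal-gap runs (overhangs where one sequence has ended) are
#' excluded, so amplicons nested inside longer ones are compared over the
#' shared span only. `N` never counts as a match.
#'
#' @param s1,s2 nucleotide strings over A,C,G,T,N.
#' @param match,mismatch,gap_open,gap_extend alignment scoring.
#' @param definition `"exclude_terminal_gaps"` (default),
#'   `"include_terminal_gaps"`, or `"shorter_length"` (matches over the
#'   shorter sequence's length).
#' @return identity fraction in \[0,1\].
#' @export
pairwise_identity <- function(s1, s2, match = 5, mismatch = -4,
                              gap_open = -10, gap_extend = -1,
                              definition = c("exclude_terminal_gaps",
                                             "include_terminal_gaps",
                                             "shorter_length")) {
  definition <- match.arg(definition)
  if (!nzchar(s1) || !nzchar(s2)) abort_fmt("empty sequence")
  alph <- c("A", "C", "G", "T", "N")
  sub <- matrix(mismatch, 5, 5, dimnames = list(alph, alph))
  diag(sub) <- match
  sub["N", ] <- mismatch; sub[, "N"] <- mismatch
  aln <- Biostrings::pairwiseAlignment(
    s1, s2, type = "global", substitutionMatrix = sub,
    gapOpening = abs(gap_open), gapExtension = abs(gap_extend))
  a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  gap_a <- a == "-"
  gap_b <- b == "-"
  cols <- seq_along(a)
  if (definition == "exclude_terminal_gaps") {
    core_a <- which(!gap_a)
    core_b <- which(!gap_b)
    lo <- max(min(core_a), min(core_b))
    hi <- min(max(core_a), max(core_b))
    if (lo > hi) return(0)
    cols <- lo:hi
  }
  matches <- sum(a[cols] == b[cols] & a[cols] != "-" & a[cols] != "N")
  denom <- switch(definition,
                  shorter_length = min(sum(!gap_a), sum(!gap_b)),
                  length(cols))
  matches / denom
}

#' Greedy centroid clustering at a fixed identity threshold
#'
#' Sequences are processed in decreasing abundance (ties broken by longer
#' sequence, then lexicographic id); each sequence joins the first existing
#' centroid, in founding order, with identity at or above the threshold, and
#' otherwise founds a new centroid.
#'
#' @param seqs named character vector of (dereplicated) sequences.
#' @param abundance named numeric abundances (default 1 per sequence).
#' @param threshold identity threshold in (0,1\]; default 0.97.
#' @param ... scoring arguments passed to [pairwise_identity()].
#' @return list of class `otu_map`: `threshold`, `centroids` (otu_id ->
#'   centroid feature id), `membership` (feature_id -> otu_id).
#' @export
greedy_cluster <- function(seqs, abundance = NULL, threshold = 0.97, ...) {
  if (threshold <= 0 || threshold > 1) abort_fmt("threshold must lie in (0,1]")
  if (is.null(abundance)) abundance <- setNames(rep(1, length(seqs)), names(seqs))
  ord <- order(-abundance[names(seqs)], -nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  centroid_ids <- character()
  membership <- setNames(character(length(seqs)), names(seqs))
  for (id in names(seqs)) {
    assigned <- FALSE
    for (cid in centroid_ids) {
      if (pairwise_identity(seqs[[id]], seqs[[cid]], ...) >= threshold) {
        membership[id] <- membership[cid]
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      centroid_ids <- c(centroid_ids, id)
      membership[id] <- sprintf("OTU%d", length(centroid_ids))
    }
  }
  structure(list(threshold = threshold,
                 centroids = setNames(centroid_ids,
                                      sprintf("OTU%d", seq_along(centroid_ids))),
                 membership = membership),
            class = "otu_map")
}

#' Cross-dataset OTU overlap
#'
#' Counts, for every subset of datasets, the OTUs whose member features span
#' exactly that subset (the cells of a Venn diagram), plus per-dataset
#' totals.
#'
#' @param membership named vector feature_id -> otu_id (from [greedy_cluster()]).
#' @param dataset_labels list or vector mapping each feature id to one or
#'   more dataset labels.
#' @return list: `subset_counts` (named by `+`-joined sorted dataset labels)
#'   and `totals` (OTUs containing at least one feature per dataset).
#' @export
shared_otus <- function(membership, dataset_labels) {
  if (is.character(dataset_labels))
    dataset_labels <- as.list(dataset_labels)
  missing <- setdiff(names(membership), names(dataset_labels))
  if (length(missing))
    abort_fmt("features without a dataset label: %s", paste(missing, collapse = ", "))
  otu_sets <- lapply(split(names(membership), membership), function(feats)
    sort(unique(unlist(dataset_labels[feats]))))
  keys <- vapply(otu_sets, paste, "", collapse = "+")
  subset_counts <- table(keys)
  datasets <- sort(unique(unlist(otu_sets)))
  totals <- vapply(datasets, function(d)
    sum(vapply(otu_sets, function(s) d %in% s, TRUE)), 0)
  list(subset_counts = setNames(as.integer(subset_counts), names(subset_counts)),
       totals = setNames(as.integer(totals), datasets))
}
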