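#' Convert counts to per-sample relative abundance
#'
#' Each row is divided by its row sum; all-zero samples stay all-zero.
#'
#' @param counts count matrix, samples x features.
#' @return numeric matrix of fractions in \[0,1\], same dimnames.
#' @export
to_relative_abundance <- function(counts) {
  validate_count_table(counts)
  tot <- rowSums(counts)
  rel <- counts / ifelse(tot > 0, tot, 1)
  storage.mode(rel) <- "double"
  rel
}

#' Neighbouring wells on a 96-well plate
#'
#' @param well a single well label.
#' @param scheme `"edge8"` (orthogonal + diagonal, the default) or `"edge4"`
#'   (orthogonal only); neighbours outside the 8 x 12 grid are dropped.
#' @return character vector of neighbouring well labels.
#' @export
adjacent_wells <- function(well, scheme = c("edge8", "edge4")) {
  scheme <- match.arg(scheme)
  pw <- parse_well(well)
  if (nrow(pw) != 1L) abort_fmt("adjacent_wells expects a single well")
  offs <- if (scheme == "edge4") {
    cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  } else {
    as.matrix(expand.grid(dr = -1:1, dc = -1:1))[-5L, , drop = FALSE]
  }
  r <- pw$row + offs[, 1L]
  co <- pw$col + offs[, 2L]
  keep <- r >= 1L & r <= 8L & co >= 1L & co <= 12L
  paste0(LETTERS[r[keep]], co[keep])
}

#' Plate-adjacency contamination filter
#'
#' Zeroes any feature whose relative abundance in a well is less than
#' `adjacency_ratio` (default 10%) times the maximum relative abundance of
#' that feature in any occupied adjacent well. All comparisons are evaluated
#' simultaneously against the input table, so the result is independent of
#' well order. Samples without a layout entry pass through unfiltered with a
#' warning (or an error when `strict = TRUE`).
#'
#' @param rel relative-abundance matrix, samples x features.
#' @param layout plate layout (see [plate_layout()]).
#' @param adjacency_ratio fraction in (0,1); default 0.10.
#' @param scheme adjacency scheme, `"edge8"` or `"edge4"`.
#' @param strict error (rather than warn) on samples missing from the layout.
#' @return list with `rel` (filtered matrix) and `report` (data.frame of
#'   zeroed entries: sample_id, feature_id, rule, value, adjacent_sample,
#'   adjacent_value).
#' @export
apply_adjacency_filter <- function(rel, layout, adjacency_ratio = 0.10,
                                   scheme = c("edge8", "edge4"),
                                   strict = FALSE) {
  scheme <- match.arg(scheme)
  if (!is.numeric(adjacency_ratio) || adjacency_ratio <= 0 || adjacency_ratio >= 1)
    abort_fmt("adjacency_ratio must lie in (0,1)")
  samples <- rownames(rel)
  unmatched <- setdiff(samples, layout$sample_id)
  if (length(unmatched)) {
    if (strict)
      abort_fmt("samples missing from plate layout: %s",
                paste(unmatched, collapse = ", "))
    warning(sprintf("samples missing from plate layout pass through unfiltered: %s",
                    paste(unmatched, collapse = ", ")))
  }
  well_of <- setNames(layout$well, layout$sample_id)
  sample_of_well <- setNames(layout$sample_id, layout$well)
  out <- rel
  rows <- list()
  for (s in setdiff(samples, unmatched)) {
    nb_wells <- adjacent_wells(well_of[[s]], scheme)
    nb_samples <- intersect(unname(sample_of_well[nb_wells]), samples)
    if (!length(nb_samples)) next
    nb <- rel[nb_samples, , drop = FALSE]
    nb_max <- apply(nb, 2L, max)
    hit <- which(rel[s, ] > 0 & rel[s, ] < adjacency_ratio * nb_max)
    if (!length(hit)) next
    out[s, hit] <- 0
    src <- nb_samples[apply(nb[, hit, drop = FALSE], 2L, which.max)]
    rows[[s]] <- data.frame(
      sample_id = s, feature_id = colnames(rel)[hit], rule = "adjacency",
      value = unname(rel[s, hit]), adjacent_sample = src,
      adjacent_value = unname(nb_max[hit]), stringsAsFactors = FALSE)
  }
  report <- if (length(rows)) do.call(rbind, rows) else empty_filter_report()
  rownames(report) <- NULL
  list(rel = out, report = report)
}

empty_filter_report <- function() {
  data.frame(sample_id = character(), feature_id = character(),
             rule = character(), value = numeric(),
             adjacent_sample = character(), adjacent_value = numeric(),
             stringsAsFactors = FALSE)
}

#' Relative-abundance floor filter
#'
#' Zeroes entries with relative abundance strictly below `abundance_floor`
#' (default 0.2%); entries exactly at the floor are retained. The table is
#' not renormalized afterwards.
#'
#' @param rel relative-abundance matrix.
#' @param abundance_floor fraction in \[0,1); default 0.002.
#' @return list with `rel` and `report` as in [apply_adjacency_filter()].
#' @export
apply_abundance_floor <- function(rel, abundance_floor = 0.002) {
  if (!is.numeric(abundance_floor) || abundance_floor < 0 || abundance_floor >= 1)
    abort_fmt("abundance_floor must lie in [0,1)")
  hit <- which(rel > 0 & rel < abundance_floor, arr.ind = TRUE)
  out <- rel
  report <- empty_filter_report()
  if (nrow(hit)) {
    report <- data.frame(
      sample_id = rownames(rel)[hit[, 1L]], feature_id = colnames(rel)[hit[, 2L]],
      rule = "floor", value = rel[hit], adjacent_sample = NA_character_,
      adjacent_value = NA_real_, stringsAsFactors = FALSE)
    out[hit] <- 0
  }
  list(rel = out, report = report)
}

#' Run the full decontamination sequence on a count table
#'
#' Relative abundance is computed over all reads (host included), the
#' adjacency filter is applied, then the abundance floor; host (and
#' optionally organelle) features are excluded afterwards.
#'
#' @param counts count matrix, samples x features.
#' @param layout plate layout.
#' @param tax taxonomy table covering every feature.
#' @param adjacency_ratio,abundance_floor,scheme filter parameters.
#' @param exclude which flagged classes to drop after filtering
#'   (`"host"`, `"organelle"`, or `"both"`).
#' @return list: `rel` (filtered, host-excluded relative abundances),
#'   `rel_all` (filtered, before exclusion), `report` (combined filter
#'   report), `excluded` (per-sample removed-read totals from [exclude_features()]).
#' @export
decontaminate <- function(counts, layout, tax,
                          adjacency_ratio = 0.10, abundance_floor = 0.002,
                          scheme = c("edge8", "edge4"),
                          exclude = c("host", "organelle", "both")) {
  exclude <- match.arg(exclude)
  scheme <- match.arg(scheme)
  rel <- to_relative_abundance(counts)
  adj <- apply_adjacency_filter(rel, layout, adjacency_ratio, scheme)
  flo <- apply_abundance_floor(adj$rel, abundance_floor)
  ex <- exclude_features(counts, tax, which = exclude)
  keep <- colnames(ex$counts)
  list(rel = flo$rel[, keep, drop = FALSE], rel_all = flo$rel,
       report = rbind(adj$report, flo$report), excluded = ex$excluded)
}

#' Exclude host and/or organelle features from a count table
#'
#' @param counts count matrix.
#' @param tax taxonomy table with `is_host`/`is_organelle` flags; every
#'   feature of `counts` must have a row.
#' @param which `"host"`, `"organelle"`, or `"both"`.
#' @return list: `counts` restricted to retained features, and `excluded`, a
#'   data.frame of per-sample removed-read totals per class (`host_reads`,
#'   `organelle_reads`).
#' @export
exclude_features <- function(counts, tax, which = c("host", "organelle", "both")) {
  which <- match.arg(which)
  missing <- setdiff(colnames(counts), tax$feature_id)
  if (length(missing))
    abort_fmt("features missing from taxonomy: %s", paste(missing, collapse = ", "))
  flag <- tax[match(colnames(counts), tax$feature_id), ]
  host <- flag$is_host
  org <- flag$is_organelle
  drop <- switch(which, host = host, organelle = org, both = host | org)
  excluded <- data.frame(
    sample_id = rownames(counts),
    host_reads = if (which != "organelle") rowSums(counts[, host, drop = FALSE]) else 0,
    organelle_reads = if (which != "host") rowSums(counts[, org, drop = FALSE]) else 0,
    row.names = NULL, stringsAsFactors = FALSE)
  list(counts = counts[, !drop, drop = FALSE], excluded = excluded)
}

#' Normalize heterotroph counts by host reads
#'
#' Each heterotroph count is divided by the sample's host-assigned read
#' total. Samples with zero host reads are emitted as missing (all-NA rows)
#' and flagged, never as infinities.
#'
#' @param het_counts heterotroph count matrix, samples x features.
#' @param host_totals named numeric vector of host reads per sample (names
#'   must cover the samples of `het_counts`).
#' @return list: `ratios` (numeric matrix), `flagged` (sample ids with zero
#'   host reads).
#' @export
host_normalize <- function(het_counts, host_totals) {
  samples <- rownames(het_counts)
  missing <- setdiff(samples, names(host_totals))
  if (length(missing))
    abort_fmt("host totals missing for samples: %s", paste(missing, collapse = ", "))
  ht <- host_totals[samples]
  flagged <- samples[ht <= 0]
  ratios <- het_counts / ifelse(ht > 0, ht, NA_real_)
  list(ratios = ratios, flagged = flagged)
}

#' Calibrate the abundance floor against a mock community
#'
#' The recommended floor is the largest relative abundance attained, in any
#' mock sample, by a feature outside the design's member set — i.e. the
#' smallest threshold that removes every observed contaminant (0 if the mock
#' is clean).
#'
#' @param observed count matrix of the sequenced mock replicates.
#' @param design a [mock_design()].
#' @return list: `recommended_floor`, and `report`, a data.frame of
#'   non-member features with their maximum relative abundance and whether
#'   the 0.2% default would remove them everywhere.
#' @export
calibrate_floor <- function(observed, design) {
  members <- design$member_ids
  if (!length(intersect(colnames(observed), members)))
    abort_fmt("no overlap between observed features and mock design members")
  rel <- to_relative_abundance(observed)
  contam <- setdiff(colnames(observed), members)
  if (!length(contam)) {
    return(list(recommended_floor = 0,
                report = data.frame(feature_id = character(), max_rel = numeric(),
                                    removed_by_default_floor = logical(),
                                    stringsAsFactors = FALSE)))
  }
  max_rel <- apply(rel[, contam, drop = FALSE], 2L, max)
  list(recommended_floor = max(max_rel),
       report = data.frame(feature_id = contam, max_rel = unname(max_rel),
                           removed_by_default_floor = unname(max_rel < 0.002),
                           stringsAsFactors = FALSE))
}
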