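#' Taxon prevalence across cultures, by host partition
#'
#' Aggregates features to a taxonomic rank (a taxon is present in a culture
#' when at least one member feature is) and reports the fraction of cultures
#' containing it, overall and within each partition (host genus).
#'
#' @param presence logical or numeric matrix, cultures x features.
#' @param tax taxonomy table covering the features.
#' @param rank rank column to aggregate at (`"phylum"`, `"class"`, `"genus"`, ...).
#' @param partition named vector of partition labels (e.g. host genus) per
#'   culture.
#' @return data.frame: taxon, overall fraction, one fraction column per
#'   partition level, plus the underlying presence counts.
#' @export
prevalence <- function(presence, tax, rank = "genus", partition) {
  pres <- as.matrix(presence) > 0
  if (!rank %in% names(tax)) abort_fmt("unknown rank: %s", rank)
  missing <- setdiff(colnames(pres), tax$feature_id)
  if (length(missing))
    abort_fmt("features missing from taxonomy: %s", paste(missing, collapse = ", "))
  part <- align_grouping(pres, partition)
  taxon <- tax[[rank]][match(colnames(pres), tax$feature_id)]
  keep <- !is.na(taxon) & nzchar(taxon)
  taxa <- sort(unique(taxon[keep]))
  # culture x taxon presence: union over member features
  tp <- vapply(taxa, function(tx)
    rowSums(pres[, keep & taxon == tx, drop = FALSE]) > 0,
    logical(nrow(pres)))
  tp <- matrix(tp, nrow = nrow(pres),
               dimnames = list(rownames(pres), taxa))
  out <- data.frame(taxon = taxa, overall = colMeans(tp),
                    stringsAsFactors = FALSE, row.names = NULL)
  for (lev in levels(part)) {
    out[[lev]] <- colMeans(tp[part == lev, , drop = FALSE])
    out[[paste0("n_", lev)]] <- colSums(tp[part == lev, , drop = FALSE])
  }
  attr(out, "partition_sizes") <- table(part)
  attr(out, "taxon_presence") <- tp
  out
}

#' Per-taxon prevalence contingency tables and Fisher tests
#'
#' For a two-level partition, builds the 2x2 present/absent table per taxon,
#' applies the two-sided Fisher exact test, and adjusts across taxa.
#'
#' @param prev result of [prevalence()] over a two-level partition.
#' @param correction a [stats::p.adjust] method; default `"bonferroni"`.
#' @return data.frame: taxon, per-partition present/absent counts, p_value,
#'   p_adjusted, odds_ratio.
#' @export
prevalence_contingency <- function(prev, correction = "bonferroni") {
  sizes <- attr(prev, "partition_sizes")
  if (length(sizes) != 2L) abort_fmt("need exactly two partitions")
  part <- names(sizes)
  rows <- lapply(prev$taxon, function(tx) {
    pa <- prev[prev$taxon == tx, paste0("n_", part[1L])]
    pb <- prev[prev$taxon == tx, paste0("n_", part[2L])]
    tab <- matrix(c(pa, sizes[[1L]] - pa, pb, sizes[[2L]] - pb), 2L, 2L,
                  byrow = TRUE)
    ft <- fisher_exact_2x2(tab)
    data.frame(taxon = tx,
               present_a = pa, absent_a = sizes[[1L]] - pa,
               present_b = pb, absent_b = sizes[[2L]] - pb,
               odds_ratio = ft$odds_ratio, p_value = ft$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[2:5] <- c(paste0("present_", part[1L]), paste0("absent_", part[1L]),
                       paste0("present_", part[2L]), paste0("absent_", part[2L]))
  out$p_adjusted <- p.adjust(out$p_value, method = correction)
  out
}

#' Per-site OTU relative abundance over non-host reads
#'
#' Each OTU count is divided by the site's non-host read total
#' (`total_reads - host_reads`); sites with no non-host reads are emitted as
#' missing.
#'
#' @param site_table list with `sites` (data.frame incl. `host_reads`,
#'   `total_reads`) and `counts` (sites x OTUs), as from [simulate_sites()].
#' @return list: `fractions` (sites x OTUs; NA rows for flagged sites),
#'   `flagged` (site ids with zero non-host reads).
#' @export
site_relative_abundance <- function(site_table) {
  s <- site_table$sites
  denom <- s$total_reads - s$host_reads
  flagged <- s$site_id[denom <= 0]
  frac <- site_table$counts / ifelse(denom > 0, denom, NA_real_)
  list(fractions = frac, flagged = flagged)
}

#' Log10 transform for display with a zero floor
#'
#' @param fractions numeric matrix of fractions.
#' @param floor value substituted for zeros before taking log10.
#' @return log10-transformed matrix.
#' @export
log10_with_floor <- function(fractions, floor = 1e-6) {
  log10(pmax(fractions, floor))
}

#' Classify OTU ocean distributions by site occupancy
#'
#' Occupancy is the fraction of (non-missing) sites where the OTU's fraction
#' exceeds `detection_floor`; an OTU is Cosmopolitan at or above `cut_cosmo`,
#' Sparse at or below `cut_sparse`, Intermediate otherwise. The cut points
#' are reported alongside every classification.
#'
#' @param site_table as in [site_relative_abundance()].
#' @param cut_cosmo,cut_sparse occupancy cut points (defaults 0.75 / 0.25).
#' @param detection_floor minimum fraction counting as detected (default 0,
#'   i.e. any read).
#' @return data.frame: otu_id, occupancy, label; cut points as attributes.
#' @export
classify_distribution <- function(site_table, cut_cosmo = 0.75,
                                  cut_sparse = 0.25, detection_floor = 0) {
  if (!nrow(site_table$sites)) abort_fmt("need at least one site")
  frac <- site_relative_abundance(site_table)$fractions
  occ <- colMeans(frac > detection_floor, na.rm = TRUE)
  label <- ifelse(occ >= cut_cosmo, "Cosmopolitan",
                  ifelse(occ <= cut_sparse, "Sparse", "Intermediate"))
  structure(data.frame(otu_id = colnames(frac), occupancy = unname(occ),
                       label = unname(label), stringsAsFactors = FALSE),
            cut_cosmo = cut_cosmo, cut_sparse = cut_sparse,
            detection_floor = detection_floor)
}

#' Rank correlation of an OTU with combined host abundance across sites
#'
#' Spearman correlation between the OTU's non-host-normalized site fraction
#' and the combined picocyanobacterial (host) read fraction; sites where the
#' OTU is absent enter as ties at the bottom of the ranking.
#'
#' @param site_table as in [site_relative_abundance()].
#' @param otu OTU id.
#' @return [spearman_cor()] result (`status = "constant"` when the OTU does
#'   not vary across sites).
#' @export
host_coupling <- function(site_table, otu) {
  if (!otu %in% colnames(site_table$counts)) abort_fmt("unknown OTU: %s", otu)
  frac <- site_relative_abundance(site_table)$fractions[, otu]
  host <- site_table$sites$host_reads / site_table$sites$total_reads
  keep <- is.finite(frac) & is.finite(host)
  if (sum(keep) < 3L) abort_fmt("need at least 3 sites with defined values")
  spearman_cor(frac[keep], host[keep])
}

#' Shared-OTU overlap above versus below a depth cut
#'
#' Pools the OTUs detected at sites above (depth <= cut) and below
#' (depth > cut) the cut, marks each pool member as shared when it occurs in
#' the culture OTU set, and tests the 2x2 table
#' `[[shared_below, unshared_below], [shared_above, unshared_above]]` with
#' the two-sided Fisher exact test.
#'
#' @param site_table as in [site_relative_abundance()].
#' @param culture_otus character vector of OTU ids found in cultures.
#' @param depth_cut depth cut in metres (default 200; sites exactly at the
#'   cut count as above).
#' @return list: `table` (2x2 integer matrix), `p_value`, `odds_ratio`,
#'   per-side shared fractions.
#' @export
depth_partition_overlap <- function(site_table, culture_otus, depth_cut = 200) {
  depth <- site_table$sites$depth_m
  below <- depth > depth_cut
  if (all(below) || !any(below))
    abort_fmt("need sites on both sides of the %g m cut", depth_cut)
  pool <- function(idx) colnames(site_table$counts)[
    colSums(site_table$counts[idx, , drop = FALSE]) > 0]
  below_otus <- pool(below)
  above_otus <- pool(!below)
  tab <- matrix(c(sum(below_otus %in% culture_otus),
                  sum(!below_otus %in% culture_otus),
                  sum(above_otus %in% culture_otus),
                  sum(!above_otus %in% culture_otus)),
                2L, 2L, byrow = TRUE,
                dimnames = list(c("below", "above"), c("shared", "unshared")))
  ft <- fisher_exact_2x2(tab)
  list(table = tab, p_value = ft$p_value, odds_ratio = ft$odds_ratio,
       shared_fraction_below = tab["below", "shared"] / max(1, sum(tab["below", ])),
       shared_fraction_above = tab["above", "shared"] / max(1, sum(tab["above", ])))
}
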