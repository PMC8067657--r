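#!/usr/bin/env Rscript
# Calibrate the relative-abundance floor on the mock communities, then run
# the full decontamination sequence on the simulated plate: adjacency filter
# (10% of the maximum in an adjacent well), 0.2% floor, host exclusion.
# Run analysis/01_simulate_data.R first.

suppressPackageStartupMessages(library(phycobycatch))
data_dir <- "results/data"
out <- "results/decontam"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

counts <- read_count_table(file.path(data_dir, "plate_counts.tsv"))
layout <- read_plate_layout(file.path(data_dir, "plate_layout.csv"))
tax <- read_taxonomy(file.path(data_dir, "taxonomy.tsv"))

# floor calibration: largest non-member relative abundance across mock reps
for (scheme in c("equimolar", "twofold_series")) {
  mock <- read_count_table(file.path(data_dir, sprintf("mock_%s.tsv", scheme)))
  cal <- calibrate_floor(mock, mock_design(scheme = scheme))
  message(sprintf("mock %s: recommended floor %.4f%% (default 0.2%% %s)",
                  scheme, 100 * cal$recommended_floor,
                  if (cal$recommended_floor <= 0.002) "is sufficient" else "would miss some")) # nolint
  write.table(cal$report, file.path(out, sprintf("floor_calibration_%s.tsv", scheme)),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

dec <- decontaminate(counts, layout, tax,
                     adjacency_ratio = 0.10, abundance_floor = 0.002,
                     scheme = "edge8", exclude = "host")
write.table(dec$report, file.path(out, "filter_report.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(sample_id = rownames(dec$rel), round(dec$rel, 6)),
            file.path(out, "filtered_relabund.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(dec$excluded, file.path(out, "host_read_totals.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

by_rule <- table(dec$report$rule)
message(sprintf("zeroed %d entries (%d by adjacency, %d by floor) across %d wells",
                nrow(dec$report), by_rule[["adjacency"]], by_rule[["floor"]],
                length(unique(dec$report$sample_id))))
rich_raw <- richness_at_threshold(
  to_relative_abundance(exclude_features(counts, tax, "host")$counts), 0.002)
rich_filt <- richness_at_threshold(dec$rel, 0.002)
message(sprintf("heterotroph richness (>= 0.2%%): median %g (range %g-%g) raw, median %g (range %g-%g) filtered",
                median(rich_raw), min(rich_raw), max(rich_raw),
                median(rich_filt), min(rich_filt), max(rich_filt)))

# host-normalized heterotroph abundance (for cross-year style comparisons)
ex <- exclude_features(counts, tax, "host")
hn <- host_normalize(ex$counts,
                     setNames(ex$excluded$host_reads, ex$excluded$sample_id))
write.table(data.frame(sample_id = rownames(hn$ratios), round(hn$ratios, 6)),
            file.path(out, "host_normalized.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
if (length(hn$flagged))
  message("samples with zero host reads flagged: ", paste(hn$flagged, collapse = ", "))
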