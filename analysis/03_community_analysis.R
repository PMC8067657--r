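#!/usr/bin/env Rscript
# Community structure of the decontaminated heterotroph communities:
# richness and rarefaction, unweighted UniFrac, Ward clustering, PERMANOVA
# and beta-dispersion by host genus and simulated isolation factors,
# indicator species analysis, and Goodman-Kruskal tau between factors.
# Run analysis/01 and 02 first.

suppressPackageStartupMessages(library(phycobycatch))
data_dir <- "results/data"
out <- "results/community"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
set.seed(1)

counts <- read_count_table(file.path(data_dir, "plate_counts.tsv"))
tax <- read_taxonomy(file.path(data_dir, "taxonomy.tsv"))
tree <- read_tree(file.path(data_dir, "heterotroph_tree.nwk"))
filt <- read.table("results/decontam/filtered_relabund.tsv", header = TRUE,
                   sep = "\t", row.names = 1)
rel <- as.matrix(filt)

truth <- jsonlite::read_json(file.path(data_dir, "plate_truth.json"))
host_genus <- vapply(rownames(rel), function(s)
  tax$genus[tax$feature_id == sprintf("host%02d", match(s, rownames(rel)))], "")
# simulated isolation metadata: cruises follow plate quadrants, methods random
layout <- read_plate_layout(file.path(data_dir, "plate_layout.csv"))
cruise <- paste0("cruise", 1 + (layout$row > 4) * 2 + (layout$col > 6))
method <- sample(c("filtration", "flow_sorting", "dilution"), nrow(rel), TRUE)
meta <- data.frame(sample_id = rownames(rel), host_genus = host_genus,
                   cruise = cruise, isolation_method = method)
write.table(meta, file.path(out, "metadata.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

rich <- richness_at_threshold(rel, 0.002)
het_counts <- exclude_features(counts, tax, "host")$counts
rare <- rarefaction_richness(het_counts, depth = min(rowSums(het_counts)),
                             reps = 100, seed = 2)
write.table(data.frame(sample_id = names(rich), richness = rich,
                       rarefaction = round(rare[names(rich)], 2)),
            file.path(out, "richness.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("richness >= 0.2%%: median %g (range %g-%g); rarefaction median %.1f",
                median(rich), min(rich), max(rich), median(rare, na.rm = TRUE)))

pres <- rel > 0
d <- unweighted_unifrac(tree, pres)
write.table(data.frame(sample_id = rownames(d), round(d, 5)),
            file.path(out, "unifrac.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
hc <- ward_clustering(d)
write.table(data.frame(merge1 = hc$merge[, 1], merge2 = hc$merge[, 2],
                       height = round(hc$height, 5)),
            file.path(out, "ward_merges.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

for (factor_name in c("host_genus", "cruise", "isolation_method")) {
  g <- setNames(meta[[factor_name]], meta$sample_id)
  pm <- permanova(d, g, n_perm = 1000, seed = 3)
  bd <- beta_dispersion(d, g, n_perm = 999, seed = 3)
  message(sprintf("%s: PERMANOVA F = %.3f (p = %.3f); dispersion F = %.3f (p = %.3f)",
                  factor_name, pm$statistic, pm$p_value, bd$statistic, bd$p_value))
  if (length(unique(g)) > 2) {
    pw <- pairwise_beta_dispersion(d, g, n_perm = 999, seed = 4)
    write.table(pw, file.path(out, sprintf("pairwise_dispersion_%s.tsv", factor_name)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    message(sprintf("  pairwise dispersion: %d/%d pairs p < 0.05, %d/%d after Bonferroni",
                    sum(pw$p_value < 0.05), nrow(pw),
                    sum(pw$p_adjusted < 0.05), nrow(pw)))
  }
}

ind <- indicator_species(pres, setNames(meta$host_genus, meta$sample_id),
                         n_perm = 999, seed = 5)
ind <- ind[!is.na(ind$statistic), ]
write.table(ind, file.path(out, "indicator_species.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
sig <- ind[ind$p_adjusted < 0.05, ]
message(sprintf("indicator ASVs (adjusted p < 0.05): %d toward Synechococcus, %d toward Prochlorococcus",
                sum(sig$group == "Synechococcus"), sum(sig$group == "Prochlorococcus")))

tau_factors <- c("host_genus", "cruise", "isolation_method")
tau <- matrix(NA_real_, 3, 3, dimnames = list(tau_factors, tau_factors))
for (i in tau_factors) for (j in tau_factors)
  if (i != j) tau[i, j] <- goodman_kruskal_tau(meta[[i]], meta[[j]])
write.table(round(tau, 3), file.path(out, "goodman_kruskal_tau.tsv"),
            sep = "\t", quote = FALSE)
message("Goodman-Kruskal tau matrix written (rows explain columns)")
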