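#!/usr/bin/env Rscript
# Generate the synthetic study data: a 96-well enrichment-culture plate with
# cross-well leakage, equimolar and two-fold dilution mock communities, a
# feature phylogeny, and an ocean transect site table. Writes the standard
# text formats plus the simulation ground truth under results/data/.

suppressPackageStartupMessages(library(phycobycatch))
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

plate <- simulate_plate(plate_sim_params(n_wells = 96, pool_size = 300,
                                         leakage_range = c(0.001, 0.02),
                                         seed = 20190601))
write_count_table(plate$counts, file.path(out, "plate_counts.tsv"))
write_plate_layout(plate$layout, file.path(out, "plate_layout.csv"))
write.table(plate$taxonomy, file.path(out, "taxonomy.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(list(
  contaminants = plate$truth$contaminants,
  depths = as.list(plate$truth$depths),
  members = lapply(plate$truth$members, as.list)
), file.path(out, "plate_truth.json"), auto_unbox = TRUE, digits = NA)

message(sprintf("plate: %d wells, %d features observed, %d planted contaminant entries",
                nrow(plate$counts), sum(colSums(plate$counts) > 0),
                nrow(plate$truth$contaminants)))

for (scheme in c("equimolar", "twofold_series")) {
  mock <- simulate_mock(mock_design(scheme = scheme), depth = 1e5,
                        contaminant_max_rel = 0.0015, seed = 77)
  write_count_table(mock$counts, file.path(out, sprintf("mock_%s.tsv", scheme)))
  message(sprintf("mock %s: %d replicates, %d injected contaminant entries",
                  scheme, nrow(mock$counts), nrow(mock$truth)))
}

het <- colnames(plate$counts)[!plate$taxonomy$is_host[
  match(colnames(plate$counts), plate$taxonomy$feature_id)]]
tree <- simulate_tree(het, seed = 5)
ape::write.tree(tree, file.path(out, "heterotroph_tree.nwk"))
message(sprintf("tree: %d heterotroph tips", length(tree$tip.label)))

sites <- simulate_sites(site_sim_params(n_sites = 500, coupling_rho = 0.3,
                                        n_deep_otus = 60, seed = 9))
site_df <- cbind(sites$sites, sites$counts)
write.table(site_df, file.path(out, "ocean_sites.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(list(archetype = as.list(sites$truth$archetype),
                          coupled_otu = sites$truth$coupled_otu,
                          target_rho = sites$truth$target_rho),
                     file.path(out, "sites_truth.json"), auto_unbox = TRUE)
message(sprintf("sites: %d sites, %d OTUs, coupled OTU %s (target rho %.2f)",
                nrow(sites$sites), ncol(sites$counts),
                sites$truth$coupled_otu, sites$truth$target_rho))
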